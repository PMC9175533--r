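#' Confusion counts for a binary classifier
#'
#' Class 1 is the positive (abnormal) class. Inputs must be equal-length
#' 0/1 vectors.
#'
#' @param labels True labels.
#' @param predictions Predicted labels.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  structure(list(
    TP = sum(labels == 1 & predictions == 1),
    TN = sum(labels == 0 & predictions == 0),
    FP = sum(labels == 0 & predictions == 1),
    FN = sum(labels == 1 & predictions == 0)
  ), class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and precision from confusion counts
#'
#' `Acc = (TP+TN)/total`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Pr = TP/(TP+FP)`. A zero denominator yields `NA` for that metric
#' rather than an error.
#'
#' @param c A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named numeric vector `Acc`, `Sn`, `Sp`, `Pr`.
#' @export
basic_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  stopifnot(total >= 1)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(Acc = (c$TP + c$TN) / total,
    Sn = safe_div(c$TP, c$TP + c$FN),
    Sp = safe_div(c$TN, c$TN + c$FP),
    Pr = safe_div(c$TP, c$TP + c$FP))
}

#' Macro-averaged F-score
#'
#' Per class `j`, `F1_j = 2 * Pr_j * Sn_j / (Pr_j + Sn_j)` (harmonic mean
#' of precision and sensitivity with that class taken as positive); the
#' report is the unweighted mean over the `q` classes. A class with
#' `Pr_j + Sn_j = 0` contributes 0 with a warning.
#'
#' @param per_class_counts List of `q` confusion-count objects, one per
#'   class treated as positive.
#' @return Macro F1 in \[0, 1\].
#' @export
f_score <- function(per_class_counts) {
  q <- length(per_class_counts)
  stopifnot(q >= 1)
  f1 <- vapply(per_class_counts, function(cc) {
    m <- basic_metrics(cc)
    pr <- m[["Pr"]]; sn <- m[["Sn"]]
    if (is.na(pr)) pr <- 0
    if (is.na(sn)) sn <- 0
    if (pr + sn == 0) {
      warning("class with Pr + Sn = 0; its F1 is taken as 0", call. = FALSE)
      return(0)
    }
    2 * pr * sn / (pr + sn)
  }, numeric(1))
  mean(f1)
}

# Both per-class tallies of a binary problem (class 1 positive, then
# class 0 positive), the inputs f_score expects for macro averaging.
per_class_confusions <- function(labels, predictions) {
  list(confusion(labels, predictions),
       confusion(1 - labels, 1 - predictions))
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' `AUC = (sum of positive ranks - I_t (I_t + 1) / 2) / (I_t * I_f)` with
#' mid-ranks for ties, where `I_t` and `I_f` count positives and
#' negatives. Equals the probability that a random positive scores above a
#' random negative (ties counted one half).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  It <- sum(labels == 1)
  If <- sum(labels == 0)
  if (It == 0 || If == 0) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - It * (It + 1) / 2) / (It * If)
}

#' Full metrics report
#'
#' Computes all six reported metrics (accuracy, sensitivity, specificity,
#' precision, macro F-score, rank AUC) from labels, hard predictions and
#' scores.
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @param scores Numeric scores for AUC; when `NULL`, the hard predictions
#'   are used as scores.
#' @return A `metrics_report`: named list of the six metrics on the \[0,1\]
#'   scale.
#' @export
metrics_report <- function(labels, predictions, scores = NULL) {
  cc <- confusion(labels, predictions)
  m <- basic_metrics(cc)
  if (is.null(scores)) scores <- predictions
  rep <- list(
    Accuracy = m[["Acc"]],
    Sensitivity = m[["Sn"]],
    Specificity = m[["Sp"]],
    Precision = m[["Pr"]],
    F_score = f_score(per_class_confusions(labels, predictions)),
    AUC = auc_rank(scores, labels)
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report (%):\n")
  print(format_metrics_percent(x))
  invisible(x)
}

#' Format a metrics report as two-decimal percentages
#'
#' @param report A `metrics_report` (values in \[0,1\]) or a named list
#'   already on the percent scale with `percent = TRUE`.
#' @param percent Set to `TRUE` when `report` values are already percent.
#' @return A one-column data.frame of formatted percent strings.
#' @export
format_metrics_percent <- function(report, percent = FALSE) {
  vals <- unlist(report, use.names = TRUE)
  if (!percent) vals <- vals * 100
  data.frame(Metric = names(vals),
             Value = sprintf("%.2f", vals),
             stringsAsFactors = FALSE)
}

#' Improvement of one report over another
#'
#' Per-metric difference `optimized - baseline` in percentage points
#' (both reports taken on the same percent scale), the layout used to
#' compare a tuned model against its untuned baseline. Antisymmetric.
#'
#' @param optimized,baseline Named lists/vectors of metrics on the percent
#'   scale, with matching names.
#' @return A data.frame with columns `Metric`, `Baseline`, `Optimized`,
#'   `Improvement` (two-decimal rounding on the improvement).
#' @export
improvement <- function(optimized, baseline) {
  opt <- unlist(optimized, use.names = TRUE)
  base <- unlist(baseline, use.names = TRUE)
  if (!identical(names(opt), names(base))) {
    stop("reports must carry the same metrics in the same order", call. = FALSE)
  }
  data.frame(
    Metric = names(opt),
    Baseline = unname(base),
    Optimized = unname(opt),
    Improvement = round(unname(opt) - unname(base), 2),
    stringsAsFactors = FALSE
  )
}

#' Sample-count accounting per split and class
#'
#' Tabulates per-split and grand totals from a named list of class counts
#' per split, mirroring dataset specification tables.
#'
#' @param split_counts Named list; each element a named numeric vector of
#'   per-class counts for one split (e.g. `list(train = c(benign = 10, ...))`).
#' @return A list with `per_split` totals and the grand `total`.
#' @export
dataset_accounting <- function(split_counts) {
  if (length(split_counts) == 0) {
    return(list(per_split = numeric(0), total = 0))
  }
  per_split <- vapply(split_counts, function(x) {
    stopifnot(all(x >= 0))
    sum(x)
  }, numeric(1))
  list(per_split = per_split, total = sum(per_split))
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
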