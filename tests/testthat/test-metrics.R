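test_that("confusion tallies and symmetry", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  # flipping the predictions swaps TP<->FN and TN<->FP
  y <- as.integer(rng_runif(rng_stream(2), 100) < 0.4)
  p <- as.integer(rng_runif(rng_stream(3), 100) < 0.5)
  a <- confusion(y, p); b <- confusion(y, 1 - p)
  expect_equal(a$TP, b$FN); expect_equal(a$TN, b$FP)
  # elementwise brute-force oracle
  expect_equal(a$TP, sum(y == 1 & p == 1))
  expect_equal(a$TN, sum(y == 0 & p == 0))
  expect_equal(a$FP, sum(y == 0 & p == 1))
  expect_equal(a$FN, sum(y == 1 & p == 0))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("accuracy, sensitivity, specificity and precision formulas", {
  m <- basic_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m2 <- basic_metrics(list(TP = 40, FN = 10, TN = 45, FP = 5))
  expect_equal(m2[["Sn"]], 0.8)
  expect_equal(m2[["Sp"]], 0.9)
  expect_equal(m2[["Acc"]], 0.85)
  expect_equal(m2[["Pr"]], 8 / 9)
  expect_equal(basic_metrics(list(TP = 0, FN = 10, TN = 3, FP = 2))[["Sn"]], 0)
  # zero denominator yields NA, never an error
  expect_true(is.na(basic_metrics(list(TP = 0, FN = 0, TN = 4, FP = 1))[["Sn"]]))
})

test_that("accuracy is the prevalence-weighted blend of Sn and Sp", {
  rng <- rng_stream(12)
  for (i in 1:20) {
    y <- as.integer(rng_runif(rng, 60) < 0.35)
    p <- as.integer(rng_runif(rng, 60) < 0.5)
    if (length(unique(y)) < 2) next
    m <- basic_metrics(confusion(y, p))
    prev <- mean(y)
    expect_equal(m[["Acc"]], prev * m[["Sn"]] + (1 - prev) * m[["Sp"]])
  }
})

test_that("macro F-score averages per-class harmonic means", {
  expect_equal(f_score(list(list(TP = 10, TN = 10, FP = 0, FN = 0))), 1)
  # Pr = Sn = 0.5 gives F1 = 0.5
  expect_equal(f_score(list(list(TP = 5, FP = 5, FN = 5, TN = 5))), 0.5)
  # classes with F1 1.0 and 0.5 average to 0.75
  expect_equal(f_score(list(list(TP = 4, TN = 4, FP = 0, FN = 0),
                            list(TP = 5, FP = 5, FN = 5, TN = 5))), 0.75)
  expect_warning(f0 <- f_score(list(list(TP = 0, FP = 0, FN = 5, TN = 5))),
                 "0")
  expect_equal(f0, 0)
})

test_that("rank AUC handles separations and total ties", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_rank(1:4, rep(1, 4)), "both classes")
})

test_that("rank AUC equals brute-force pair counting", {
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  rng <- rng_stream(42)
  for (i in 1:25) {
    n <- 50
    scores <- round(rng_runif(rng, n), 1)  # coarse grid forces ties
    labels <- as.integer(rng_runif(rng, n) < 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auc_rank(scores, labels), pair_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("improvement tables difference on the percent scale", {
  opt <- c(Accuracy = 98.32); base <- c(Accuracy = 90.11)
  expect_equal(improvement(opt, base)$Improvement, 8.21)
  opt2 <- c(Accuracy = 98.88); base2 <- c(Accuracy = 87.50)
  expect_equal(improvement(opt2, base2)$Improvement, 11.38)
  # identical reports give all zeros; antisymmetry
  r <- c(Accuracy = 95.5, AUC = 97.2)
  expect_true(all(improvement(r, r)$Improvement == 0))
  s <- c(Accuracy = 91.1, AUC = 94.3)
  expect_equal(improvement(r, s)$Improvement, -improvement(s, r)$Improvement)
  expect_error(improvement(c(a = 1), c(b = 1)), "same metrics")
})

test_that("dataset accounting totals splits and classes", {
  cbis <- dataset_accounting(list(
    train = c(benign = 1824, cancer = 1873),
    test = c(benign = 783, cancer = 803)))
  expect_equal(cbis$total, 5283)
  expect_equal(unname(cbis$per_split), c(1824 + 1873, 783 + 803))
  mias <- dataset_accounting(list(train = c(all = 904), test = c(all = 386)))
  expect_equal(mias$total, 1290)
  expect_equal(dataset_accounting(list())$total, 0)
})

test_that("metrics report carries the six reported metrics in [0,1]", {
  rng <- rng_stream(5)
  y <- as.integer(rng_runif(rng, 40) < 0.5)
  y[1:2] <- c(0L, 1L)
  s <- rng_runif(rng, 40)
  rep <- metrics_report(y, as.integer(s > 0.5), s)
  expect_named(rep, c("Accuracy", "Sensitivity", "Specificity", "Precision",
                      "F_score", "AUC"))
  vals <- unlist(rep)
  expect_true(all(vals >= 0 & vals <= 1))
  fmt <- format_metrics_percent(rep)
  expect_match(fmt$Value, "^\\d+\\.\\d{2}$")
})
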