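#' Synthetic two-class grayscale image set
#'
#' Desk-scale stand-in for a mammography dataset. Class 0 images are
#' smoothed Gaussian background texture; class 1 images carry the same
#' texture plus a bright elliptical blob of random position, size and
#' eccentricity whose contrast (in units of the background noise SD) is the
#' `separation` parameter. At `separation >= 3` the classes are separable
#' by a simple mean-intensity threshold, which gives the harness a graded
#' difficulty dial. Classes are balanced and generation is bit-reproducible
#' under a fixed seed.
#'
#' @param n_per_class Images per class, `>= 1`.
#' @param size Image side length in pixels, `>= 16` (default 64).
#' @param separation Blob contrast in background-noise SDs, `>= 0`.
#' @param seed Integer seed.
#' @return A `labeled_image_set`: list with `images` (list of `size x size`
#'   matrices in \[0,1\]), `labels` (0/1 vector), `seed`, `separation`.
#' @export
generate_image_dataset <- function(n_per_class, size = 64, separation = 4,
                                   seed = 1) {
  stopifnot(n_per_class >= 1, size >= 16, separation >= 0)
  rng <- rng_stream(seed)
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  noise_sd <- 0.1
  images <- vector("list", n)
  for (i in seq_len(n)) {
    img <- matrix(rng_rnorm(rng, size * size) * noise_sd + 0.35, size, size)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1.5))
    if (labels[i] == 1L) {
      img <- img + blob_mask(size, rng) * (separation * noise_sd)
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
  }
  structure(list(images = images, labels = labels, seed = seed,
                 separation = separation, size = size),
            class = "labeled_image_set")
}

# Smooth elliptical bump with unit peak height: random centre (central
# 60% of the frame), random radii 12-25% of the side, random orientation.
blob_mask <- function(size, rng) {
  u <- rng_runif(rng, 5)
  cx <- size * (0.2 + 0.6 * u[1])
  cy <- size * (0.2 + 0.6 * u[2])
  rx <- size * (0.12 + 0.13 * u[3])
  ry <- size * (0.12 + 0.13 * u[4])
  theta <- pi * u[5]
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  dx <- xs - cx
  dy <- ys - cy
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  d2 <- (xr / rx)^2 + (yr / ry)^2
  exp(-d2 * 2)
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set: %d images (%dx%d), %d per class, separation %g, seed %d\n",
              length(x$images), x$size, x$size, sum(x$labels == 0),
              x$separation, x$seed))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits an image set preserving class proportions to within one item;
#' the two parts are disjoint and exhaustive, and the split is reproducible
#' under a fixed seed.
#'
#' @param set A `labeled_image_set`.
#' @param test_fraction Fraction held out, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with `train` and `test`, each a `labeled_image_set`.
#' @export
stratified_split <- function(set, test_fraction, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  rng <- rng_stream(seed)
  test_idx <- integer(0)
  for (cls in sort(unique(set$labels))) {
    idx <- which(set$labels == cls)
    k <- round(length(idx) * test_fraction)
    if (k >= 1) test_idx <- c(test_idx, rng_sample(rng, idx, k))
  }
  subset_set <- function(idx) {
    structure(list(images = set$images[idx], labels = set$labels[idx],
                   seed = set$seed, separation = set$separation,
                   size = set$size),
              class = "labeled_image_set")
  }
  list(train = subset_set(setdiff(seq_along(set$labels), test_idx)),
       test = subset_set(sort(test_idx)))
}

#' Write / read an image set in the class-per-subdirectory PNG layout
#'
#' The on-disk layout is `root/<split>/<class_a|class_b>/*.png`; class_a is
#' label 0, class_b label 1. `read_image_dataset` reports per-class counts
#' as an attribute.
#'
#' @param set A `labeled_image_set`.
#' @param root Dataset root directory.
#' @param split Split subdirectory name (e.g. `"train"` or `"test"`).
#' @return The split directory (write) or a `labeled_image_set` (read).
#' @export
write_image_dataset <- function(set, root, split = "train") {
  for (cls in c("class_a", "class_b")) {
    dir.create(file.path(root, split, cls), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(set$images)) {
    cls <- if (set$labels[i] == 0) "class_a" else "class_b"
    png::writePNG(set$images[[i]],
                  file.path(root, split, cls, sprintf("img_%04d.png", i)))
  }
  invisible(file.path(root, split))
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(root, split = "train") {
  base <- file.path(root, split)
  if (!dir.exists(base)) stop("no such split directory: ", base, call. = FALSE)
  images <- list(); labels <- integer(0)
  for (cls in c("class_a", "class_b")) {
    dir <- file.path(base, cls)
    files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- tryCatch(png::readPNG(f), error = function(e) {
        stop("unreadable image file: ", f, call. = FALSE)
      })
      if (length(dim(img)) == 3) img <- img[, , 1]
      images[[length(images) + 1L]] <- img
      labels <- c(labels, if (cls == "class_a") 0L else 1L)
    }
  }
  size <- if (length(images)) nrow(images[[1]]) else 0L
  out <- structure(list(images = images, labels = labels, seed = NA_integer_,
                        separation = NA_real_, size = size),
                   class = "labeled_image_set")
  attr(out, "class_counts") <- c(class_a = sum(labels == 0L),
                                 class_b = sum(labels == 1L))
  out
}

#' Mean-intensity threshold oracle
#'
#' The simplest classifier the synthetic classes admit: predict class 1
#' when an image's mean intensity exceeds a threshold chosen on the given
#' set (best split point over candidate midpoints). Used to calibrate the
#' generator and as an independent accuracy reference.
#'
#' @param set A `labeled_image_set`.
#' @return List with `threshold` and training `accuracy`.
#' @export
threshold_oracle <- function(set) {
  means <- vapply(set$images, mean, numeric(1))
  ord <- order(means)
  m <- means[ord]; y <- set$labels[ord]
  cuts <- (m[-1] + m[-length(m)]) / 2
  acc <- vapply(cuts, function(ct) mean((means > ct) == (set$labels == 1)),
                numeric(1))
  best <- which.max(acc)
  list(threshold = cuts[best], accuracy = acc[best])
}
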