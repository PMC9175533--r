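cfg_small <- function(epochs = 2) {
  classifier_config(1e-3, 8, c(0.2, 0.3, 0.4), c(60, 50, 50), epochs = epochs)
}

test_that("classifier head has the fixed eight-layer architecture", {
  cfg <- classifier_config(1e-4, 16, c(0.25, 0.35, 0.45), c(100, 80, 60))
  head <- build_head(cfg)
  expect_length(head$layers, 8)
  types <- vapply(head$layers, `[[`, character(1), "type")
  expect_equal(types, c("flatten", "dense", "dropout", "dense", "dropout",
                        "dense", "dropout", "dense"))
  dense <- Filter(function(l) l$type == "dense", head$layers)
  expect_equal(vapply(dense, `[[`, numeric(1), "units"), c(100, 80, 60, 1))
  expect_equal(vapply(dense, `[[`, character(1), "activation"),
               c("relu", "relu", "relu", "sigmoid"))
  drops <- Filter(function(l) l$type == "dropout", head$layers)
  expect_equal(vapply(drops, `[[`, numeric(1), "rate"), c(0.25, 0.35, 0.45))
})

test_that("preprocessing resizes, preserves constants and correct sizes", {
  big <- matrix(stats::runif(128 * 128), 128, 128)
  out <- preprocess_images(list(big), input_size = 32)
  expect_equal(dim(out[[1]]), c(32, 32))
  ok <- matrix(0.5, 32, 32)
  expect_equal(dim(preprocess_images(list(ok), 32)[[1]]), c(32, 32))
  # constant image stays constant through resize + median filter
  expect_true(all(abs(preprocess_images(list(matrix(0.4, 64, 64)), 32)[[1]] - 0.4) < 1e-6))
  expect_error(preprocess_images(list(matrix(NA_real_, 4, 4)), 32),
               "unreadable|non-finite")
})

test_that("stage A freezes the backbone bit-exactly", {
  d <- tiny_image_set()
  sp <- stratified_split(d, 0.25, seed = 2)
  bb <- surrogate_backbone(32, seed = 7)
  # epochs = 1 runs stage A only
  m <- train_transfer(bb, NULL, sp$train, sp$test, cfg_small(1), seed = 3)
  expect_identical(m$params$backbone, bb$blocks)
  expect_equal(m$history$stage, "A")
})

test_that("stage B unfreezes exactly the last two blocks", {
  d <- tiny_image_set()
  sp <- stratified_split(d, 0.25, seed = 2)
  bb <- surrogate_backbone(32, seed = 7)
  m <- train_transfer(bb, NULL, sp$train, sp$test, cfg_small(2), seed = 3,
                      checkpoint = FALSE)
  expect_identical(m$params$backbone[[1]], bb$blocks[[1]])
  expect_false(identical(m$params$backbone[[2]], bb$blocks[[2]]))
  expect_false(identical(m$params$backbone[[3]], bb$blocks[[3]]))
  expect_equal(m$history$stage, c("A", "B"))
})

test_that("training and fitness are pure functions of their seeds", {
  d <- tiny_image_set()
  space <- default_space()
  bb <- surrogate_backbone(32, seed = 7)
  pos <- c(-3.2, 6, 0.2, 0.3, 0.4, 60, 50, 50)
  f1 <- fitness_of_config(pos, space, d, bb, budget_epochs = 1, seed = 11)
  f2 <- fitness_of_config(pos, space, d, bb, budget_epochs = 1, seed = 11)
  expect_identical(f1, f2)
  expect_gte(f1, 0); expect_lte(f1, 1)
})

test_that("surrogate training learns separable fixture data", {
  d <- generate_image_dataset(24, size = 32, separation = 4, seed = 19)
  sp <- stratified_split(d, 0.2, seed = 1)
  bb <- surrogate_backbone(32, seed = 42)
  cfg <- classifier_config(1e-3, 8, c(0.2, 0.2, 0.2), c(100, 80, 60),
                           epochs = 5)
  m <- train_transfer(bb, NULL, sp$train, sp$test, cfg,
                      aug = augmentation_config(enabled = FALSE), seed = 1)
  expect_gte(m$history$val_acc[nrow(m$history)], 0.9)
})

test_that("augmentation transforms are train-time only constructs", {
  aug_off <- augmentation_config(enabled = FALSE)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(impaopt:::augment_image(img, aug_off, rng_stream(1)), img)
  # a warped constant image stays constant (reflect fill introduces no edges)
  cimg <- matrix(0.7, 32, 32)
  out <- impaopt:::augment_image(cimg, augmentation_config(), rng_stream(5))
  expect_true(all(abs(out - 0.7) < 1e-12))
  # warps are reproducible and stay in the intensity range
  a1 <- impaopt:::augment_image(img, augmentation_config(), rng_stream(8))
  a2 <- impaopt:::augment_image(img, augmentation_config(), rng_stream(8))
  expect_identical(a1, a2)
  expect_true(all(a1 >= min(img) - 1e-9 & a1 <= max(img) + 1e-9))
})

test_that("augmentation defaults carry the documented recipe", {
  aug <- augmentation_config()
  expect_equal(aug$shear, 0.1)
  expect_equal(aug$zoom, 0.1)
  expect_equal(aug$width_shift, 0.3)
  expect_equal(aug$height_shift, 0.3)
  expect_equal(aug$rotation, 15)
  expect_true(aug$featurewise_center)
  expect_true(aug$featurewise_std_normalization)
  expect_equal(aug$fill_mode, "reflect")
  expect_true(aug$vertical_flip && aug$horizontal_flip)
})

test_that("resnet50 backbone demands pretrained weights explicitly", {
  expect_error(make_backbone("resnet50"), "pretrained weights")
  expect_error(make_backbone("resnet50", weights_path = "/nonexistent.h5"),
               "pretrained weights")
})

test_that("an untrained zero-output head scores at chance on balanced data", {
  d <- tiny_image_set()
  bb <- surrogate_backbone(32, seed = 7)
  cfg <- cfg_small(1)
  head <- build_head(cfg)
  params <- list(backbone = bb$blocks,
                 head = impaopt:::init_head_params(head, bb$n_features,
                                                  rng_stream(3)))
  # zero the output layer: every score is exactly 0.5, predictions all
  # negative, accuracy = prevalence of the negative class = 0.5
  params$head$dense[[4]]$W[] <- 0
  scores <- impaopt:::predict_scores(params, d$images)
  expect_true(all(scores == 0.5))
  acc <- mean((scores > 0.5) == (d$labels == 1))
  expect_equal(acc, 0.5)
})
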