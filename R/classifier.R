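#' Classifier-head specification
#'
#' The replacement classifier has exactly eight layers in fixed order:
#' flatten, dense(units_1, ReLU), dropout(rate_1), dense(units_2, ReLU),
#' dropout(rate_2), dense(units_3, ReLU), dropout(rate_3), dense(1,
#' sigmoid). The three ReLU widths and the three dropout rates come from
#' the decoded hyperparameter vector. The output layer is a single sigmoid
#' unit trained with binary cross-entropy: a one-unit softmax would be
#' constant, so the sigmoid is the working reading of a one-neuron
#' two-class output.
#'
#' @param config A [classifier_config()].
#' @return A `head_spec` with a `layers` descriptor list (length 8),
#'   `dense_units` and `dropout_rates`.
#' @export
build_head <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  u <- config$dense_units; r <- config$dropout_rates
  layers <- list(
    list(type = "flatten"),
    list(type = "dense", units = u[1], activation = "relu"),
    list(type = "dropout", rate = r[1]),
    list(type = "dense", units = u[2], activation = "relu"),
    list(type = "dropout", rate = r[2]),
    list(type = "dense", units = u[3], activation = "relu"),
    list(type = "dropout", rate = r[3]),
    list(type = "dense", units = 1L, activation = "sigmoid")
  )
  structure(list(layers = layers, dense_units = u, dropout_rates = r),
            class = "head_spec")
}

#' Backbone constructors
#'
#' `surrogate_backbone()` builds the package's small fixed convolutional
#' feature extractor: three conv(3x3)-ReLU-meanpool(2x2) blocks with 4, 8
#' and 8 filters, seeded He-initialized weights, trainable in seconds on
#' fixture-sized inputs. Its "last two blocks" (the fine-tuning unit) are
#' blocks 2 and 3. `make_backbone("resnet50", ...)` is the hook for a true
#' pretrained ResNet50; without locally supplied pretrained weights it
#' raises an explicit error rather than silently substituting anything.
#'
#' @param input_size Square input side (must be divisible by 8); default 32.
#' @param seed Seed for the fixed random initialization.
#' @return A `backbone_spec` with `name`, `input_size`, `blocks` (weights),
#'   `block_boundaries` (indices of the last two, fine-tunable blocks) and
#'   `n_features`.
#' @export
surrogate_backbone <- function(input_size = 32, seed = 42) {
  stopifnot(input_size %% 8 == 0, input_size >= 16)
  rng <- rng_stream(seed)
  filters <- c(4L, 8L, 8L)
  in_ch <- 1L
  blocks <- vector("list", 3)
  for (k in 1:3) {
    blocks[[k]] <- list(W = he_init(9 * in_ch, filters[k], rng),
                        b = numeric(filters[k]))
    in_ch <- filters[k]
  }
  side <- input_size / 8
  structure(list(name = "surrogate_cnn", input_size = input_size,
                 blocks = blocks, block_boundaries = c(2L, 3L),
                 n_features = as.integer(side * side * filters[3]),
                 seed = seed),
            class = "backbone_spec")
}

#' @rdname surrogate_backbone
#' @param name `"surrogate_cnn"` or `"resnet50"`.
#' @param weights_path Path to pretrained ResNet50 weights (required for
#'   the resnet50 backbone).
#' @export
make_backbone <- function(name = c("surrogate_cnn", "resnet50"),
                          input_size = NULL, seed = 42, weights_path = NULL) {
  name <- match.arg(name)
  if (name == "surrogate_cnn") {
    return(surrogate_backbone(input_size %||% 32, seed))
  }
  if (is.null(weights_path) || !file.exists(weights_path)) {
    stop("resnet50 backbone requires locally available pretrained weights ",
         "(weights_path); none found. Use the surrogate_cnn backbone for ",
         "desk-scale runs.", call. = FALSE)
  }
  stop("resnet50 weight loading is not supported in this build; ",
       "use the surrogate_cnn backbone.", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Data-augmentation configuration
#'
#' Defaults follow the harness's mammography-style recipe: shear 0.1,
#' zoom 0.1, width/height shift fractions 0.3, rotation 15 degrees,
#' featurewise centering and SD normalization, reflect fill, and both
#' flips. All fields overridable; `enabled = FALSE` turns the random
#' transforms off entirely.
#'
#' @param shear Shear intensity (radians), sampled uniformly in +/- range.
#' @param zoom Zoom range; scale sampled in `[1 - zoom, 1 + zoom]`.
#' @param width_shift,height_shift Shift fractions of the image side.
#' @param rotation Max absolute rotation in degrees.
#' @param featurewise_center Subtract the training-set mean.
#' @param featurewise_std_normalization Divide by the training-set SD.
#' @param fill_mode Boundary fill for the affine warp (`"reflect"`).
#' @param vertical_flip,horizontal_flip Random flips with probability 1/2.
#' @param enabled Master switch for the random transforms.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(shear = 0.1, zoom = 0.1, width_shift = 0.3,
                                height_shift = 0.3, rotation = 15,
                                featurewise_center = TRUE,
                                featurewise_std_normalization = TRUE,
                                fill_mode = "reflect",
                                vertical_flip = TRUE, horizontal_flip = TRUE,
                                enabled = TRUE) {
  stopifnot(fill_mode == "reflect")
  structure(list(shear = shear, zoom = zoom, width_shift = width_shift,
                 height_shift = height_shift, rotation = rotation,
                 featurewise_center = featurewise_center,
                 featurewise_std_normalization = featurewise_std_normalization,
                 fill_mode = fill_mode, vertical_flip = vertical_flip,
                 horizontal_flip = horizontal_flip, enabled = enabled),
            class = "augmentation_config")
}

# Random affine warp of one image under the augmentation config.
# Backward mapping with bilinear sampling and reflect boundary handling.
augment_image <- function(img, aug, rng) {
  if (!aug$enabled) return(img)
  n <- nrow(img)
  u <- rng_runif(rng, 7)
  theta <- (2 * u[1] - 1) * aug$rotation * pi / 180
  s <- (2 * u[2] - 1) * aug$shear
  z <- 1 + (2 * u[3] - 1) * aug$zoom
  tx <- (2 * u[4] - 1) * aug$width_shift * n
  ty <- (2 * u[5] - 1) * aug$height_shift * n
  flip_v <- aug$vertical_flip && u[6] < 0.5
  flip_h <- aug$horizontal_flip && u[7] < 0.5
  # forward map: rotate . shear . zoom, then translate (about the centre)
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2) %*%
    matrix(c(1, 0, s, 1), 2) %*% diag(c(z, z))
  Ainv <- solve(A)
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n) - ctr        # row coordinate
  ys <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  src_x <- Ainv[1, 1] * (xs - tx) + Ainv[1, 2] * (ys - ty) + ctr
  src_y <- Ainv[2, 1] * (xs - tx) + Ainv[2, 2] * (ys - ty) + ctr
  out <- bilinear_reflect(img, src_x, src_y)
  if (flip_v) out <- out[n:1, ]
  if (flip_h) out <- out[, n:1]
  out
}

# Reflect an index vector into [1, n] (mirror boundary without repeating
# the edge sample), then bilinear-interpolate.
reflect_index <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  x <- (x - 1) %% period
  x <- ifelse(x > (n - 1), period - x, x)
  x + 1
}

bilinear_reflect <- function(img, src_x, src_y) {
  n <- nrow(img); m <- ncol(img)
  sx <- reflect_index(as.vector(src_x), n)
  sy <- reflect_index(as.vector(src_y), m)
  x0 <- pmin(floor(sx), n - 1); x1 <- x0 + 1
  y0 <- pmin(floor(sy), m - 1); y1 <- y0 + 1
  fx <- sx - x0; fy <- sy - y0
  v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y1)] * (1 - fx) * fy +
    img[cbind(x1, y1)] * fx * fy
  matrix(v, n, m)
}

#' Preprocess images for a backbone
#'
#' Resizes each image to the backbone's square input size (bilinear),
#' optionally applies a light 3x3 median denoising filter, and scales
#' intensities into \[0, 1\].
#'
#' @param images List of grayscale matrices, or a `labeled_image_set`.
#' @param input_size Target side length.
#' @param denoise Apply the 3x3 median filter (default `TRUE`).
#' @return The preprocessed list (or image set with images replaced).
#' @export
preprocess_images <- function(images, input_size, denoise = TRUE) {
  is_set <- inherits(images, "labeled_image_set")
  imgs <- if (is_set) images$images else images
  out <- lapply(imgs, function(img) {
    if (!is.matrix(img) || any(!is.finite(img))) {
      stop("unreadable or non-finite image", call. = FALSE)
    }
    if (nrow(img) != input_size || ncol(img) != input_size) {
      img <- as.matrix(EBImage::resize(EBImage::Image(img),
                                       w = input_size, h = input_size))
    }
    if (denoise) {
      img <- pmin(pmax(img, 0), 1)
      img <- as.matrix(EBImage::medianFilter(EBImage::Image(img), size = 1))
    }
    pmin(pmax(img, 0), 1)
  })
  if (is_set) {
    images$images <- out
    images$size <- input_size
    images
  } else {
    out
  }
}

#' Train the transfer-learning classifier
#'
#' Two stages. Stage A (feature extraction): every backbone parameter is
#' frozen and only the new head is trained. Stage B (fine-tuning): the
#' last two backbone blocks are unfrozen and training continues jointly.
#' The learning rate and batch size come from `config`; random
#' augmentation is applied to the training stream only. Optimization is
#' Adam with binary cross-entropy on the sigmoid output.
#'
#' @param backbone A `backbone_spec` (see [surrogate_backbone()]).
#' @param head A `head_spec` from [build_head()] (rebuilt from `config`
#'   when `NULL`).
#' @param train,validation `labeled_image_set`s (images already sized for
#'   the backbone, or they are preprocessed here).
#' @param config A [classifier_config()]; `config$epochs` is the total
#'   budget, split half/half between the stages (stage A gets the extra
#'   epoch when odd).
#' @param aug An [augmentation_config()].
#' @param seed Seed controlling initialization, shuffling, dropout and
#'   augmentation draws.
#' @param head_lr_factor Discriminative learning-rate multiplier for the
#'   freshly initialized head (default 10; the effective head rate is
#'   capped at 1e-2). The searched learning rate is the backbone
#'   fine-tuning rate; new layers conventionally train faster.
#' @param checkpoint Keep the parameters of the epoch with the highest
#'   validation accuracy instead of the last epoch's (default `TRUE`).
#' @return A `trained_model` with final parameters, per-epoch `history`,
#'   the retained validation accuracy `val_acc`, the config,
#'   normalization stats and seed.
#' @export
train_transfer <- function(backbone, head = NULL, train, validation, config,
                           aug = augmentation_config(), seed = 1,
                           head_lr_factor = 10, checkpoint = TRUE) {
  stopifnot(inherits(backbone, "backbone_spec"),
            inherits(config, "classifier_config"))
  if (is.null(head)) head <- build_head(config)
  rng <- rng_stream(seed)

  train <- preprocess_images(train, backbone$input_size)
  validation <- preprocess_images(validation, backbone$input_size)

  # featurewise normalization fitted on the training set, applied to both
  mu <- 0; sdv <- 1
  if (aug$featurewise_center) mu <- mean(unlist(lapply(train$images, mean)))
  if (aug$featurewise_std_normalization) {
    sdv <- stats::sd(unlist(train$images))
    if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1
  }
  norm1 <- function(img) (img - mu) / sdv

  params <- list(backbone = lapply(backbone$blocks, identity),
                 head = init_head_params(head, backbone$n_features, rng))
  n_epochs_a <- ceiling(config$epochs / 2)
  n_epochs_b <- config$epochs - n_epochs_a

  opt <- adam_state()
  step_t <- 0L
  history <- data.frame()
  y <- train$labels
  n_tr <- length(y)

  run_epoch <- function(stage) {
    order_idx <- rng_sample(rng, n_tr, n_tr)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    fine_tune <- stage == "B"
    keep_from <- if (fine_tune) backbone$block_boundaries[1] else 0L
    for (batch in batches) {
      B <- length(batch)
      imgs <- lapply(train$images[batch], function(im) {
        norm1(augment_image(im, aug, rng))
      })
      fwd <- lapply(imgs, function(im) {
        backbone_forward(list(blocks = params$backbone), im, keep_from)
      })
      X <- do.call(rbind, lapply(fwd, `[[`, "features"))
      masks <- lapply(1:3, function(i) {
        r <- head$dropout_rates[i]
        u <- head$dense_units[i]
        matrix(as.numeric(rng_runif(rng, B * u) >= r) / (1 - r), B, u)
      })
      acts <- head_forward(params$head, X, masks)
      p <- pmin(pmax(acts$p, 1e-12), 1 - 1e-12)
      yb <- matrix(y[batch], ncol = 1)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      if (!is.finite(loss)) {
        stop("non-finite training loss for config: lr=", config$learning_rate,
             " batch=", config$batch_size, call. = FALSE)
      }
      ep_loss <- ep_loss + loss * B
      ep_correct <- ep_correct + sum((acts$p > 0.5) == (yb == 1))

      dz4 <- (acts$p - yb) / B
      hb <- head_backward(params$head, acts, dz4, masks)
      step_t <<- step_t + 1L
      lr <- config$learning_rate
      # discriminative learning rates: the freshly initialized head trains
      # at head_lr_factor times the backbone fine-tuning rate
      lr_head <- min(lr * head_lr_factor, 1e-2)
      for (i in 1:4) {
        params$head$dense[[i]]$W <<- adam_update(
          opt, paste0("h", i, "W"), params$head$dense[[i]]$W,
          hb$grads$dense[[i]]$dW, lr_head, step_t)
        params$head$dense[[i]]$b <<- adam_update(
          opt, paste0("h", i, "b"), params$head$dense[[i]]$b,
          hb$grads$dense[[i]]$db, lr_head, step_t)
      }
      if (fine_tune) {
        acc <- NULL
        for (j in seq_len(B)) {
          g <- backbone_backward(list(blocks = params$backbone), fwd[[j]],
                                 hb$dx[j, ], keep_from)
          if (is.null(acc)) acc <- g else {
            for (k in backbone$block_boundaries) {
              acc[[k]]$dW <- acc[[k]]$dW + g[[k]]$dW
              acc[[k]]$db <- acc[[k]]$db + g[[k]]$db
            }
          }
        }
        for (k in backbone$block_boundaries) {
          params$backbone[[k]]$W <<- adam_update(
            opt, paste0("b", k, "W"), params$backbone[[k]]$W, acc[[k]]$dW, lr, step_t)
          params$backbone[[k]]$b <<- adam_update(
            opt, paste0("b", k, "b"), params$backbone[[k]]$b, acc[[k]]$db, lr, step_t)
        }
      }
    }
    c(loss = ep_loss / n_tr, acc = ep_correct / n_tr)
  }

  eval_split <- function(split) {
    scores <- predict_scores(params, split$images, norm = norm1)
    mean((scores > 0.5) == (split$labels == 1))
  }

  best_params <- NULL
  best_val <- -Inf
  log_epoch <- function(stage, ep, tr) {
    va <- eval_split(validation)
    if (checkpoint && va > best_val) {
      best_val <<- va
      best_params <<- params
    }
    history <<- rbind(history, data.frame(
      stage = stage, epoch = ep, loss = tr[["loss"]], train_acc = tr[["acc"]],
      val_acc = va))
  }
  for (ep in seq_len(n_epochs_a)) log_epoch("A", ep, run_epoch("A"))
  for (ep in seq_len(n_epochs_b)) log_epoch("B", ep, run_epoch("B"))
  if (checkpoint && !is.null(best_params)) params <- best_params

  structure(list(
    backbone_name = backbone$name,
    input_size = backbone$input_size,
    block_boundaries = backbone$block_boundaries,
    params = params,
    head_spec = head,
    config = config,
    history = history,
    val_acc = if (checkpoint) best_val else history$val_acc[nrow(history)],
    norm = c(mu = mu, sd = sdv),
    seed = seed
  ), class = "trained_model")
}

predict_scores <- function(params, images, norm = identity) {
  X <- do.call(rbind, lapply(images, function(im) {
    backbone_forward(list(blocks = params$backbone), norm(im), 0L)$features
  }))
  acts <- head_forward(params$head, X, NULL)
  as.vector(acts$p)
}

#' Predict class scores with a trained model
#'
#' @param model A `trained_model` from [train_transfer()].
#' @param images List of grayscale matrices or a `labeled_image_set`
#'   (preprocessed to the model's input size automatically).
#' @return Numeric vector of class-1 scores in (0, 1).
#' @export
predict_model <- function(model, images) {
  if (inherits(images, "labeled_image_set")) {
    images <- preprocess_images(images, model$input_size)$images
  } else {
    images <- preprocess_images(images, model$input_size)
  }
  norm1 <- function(img) (img - model$norm[["mu"]]) / model$norm[["sd"]]
  predict_scores(model$params, images, norm = norm1)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model [%s, %dpx] %d epochs, val acc %.3f\n",
              x$backbone_name, x$input_size, nrow(x$history), x$val_acc))
  invisible(x)
}

#' Hyperparameter fitness of an optimizer position
#'
#' Decodes a position in the eight-dimensional space, trains the
#' transfer-learning classifier under the evaluation budget, and returns
#' `1 - validation accuracy` (minimization orientation). The validation
#' split is a stratified 20% of the training set; the test set plays no
#' role during optimization. A training failure (non-finite loss) returns
#' the sentinel worst fitness 1.0 with a warning. The result is a pure
#' function of (position, dataset, seed, budget).
#'
#' @param position Optimizer-coordinate vector of length `Dim`.
#' @param space The search space (normally [default_space()]).
#' @param train_set `labeled_image_set` used for training + validation.
#' @param backbone A `backbone_spec`.
#' @param budget_epochs Training epochs per candidate (reduced budget
#'   during optimization; default 2).
#' @param aug An [augmentation_config()].
#' @param seed Integer seed shared across candidates.
#' @return Scalar fitness in \[0, 1\].
#' @export
fitness_of_config <- function(position, space, train_set, backbone,
                              budget_epochs = 2, aug = augmentation_config(),
                              seed = 1) {
  config <- decode_position(position, space, epochs = budget_epochs)
  split <- stratified_split(train_set, 0.2, seed = seed)
  res <- tryCatch({
    model <- train_transfer(backbone, NULL, split$train, split$test,
                            config, aug = aug, seed = seed)
    1 - model$val_acc
  }, error = function(e) {
    warning("candidate training failed (", conditionMessage(e),
            "); assigning worst fitness", call. = FALSE)
    1.0
  })
  res
}

#' Objective adapter for CNN hyperparameter search
#'
#' Wraps [fitness_of_config()] as an [objective_adapter()] over the given
#' dataset, backbone and budget.
#'
#' @inheritParams fitness_of_config
#' @return An `objective_adapter` (minimizing `1 - validation accuracy`).
#' @export
make_cnn_objective <- function(space, train_set, backbone, budget_epochs = 2,
                               aug = augmentation_config(), seed = 1) {
  objective_adapter(function(position) {
    fitness_of_config(position, space, train_set, backbone,
                      budget_epochs = budget_epochs, aug = aug, seed = seed)
  }, "minimize")
}
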