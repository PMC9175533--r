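# Minimal convolutional network engine backing the surrogate backbone and
# the dense classifier head: 3x3 same-padding convolutions via im2col,
# ReLU, 2x2 mean pooling, dense layers with inverted dropout, a sigmoid
# output with binary cross-entropy, and Adam updates. Written against
# small inputs (32x32-ish) where plain R matrix algebra is fast enough.

# --- im2col convolution (kernel 3, pad 1, stride 1) ------------------------

# x: H x W x C array -> list(out = H x W x F array, cols = (H*W) x (9C))
conv_forward <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  padded <- array(0, dim = c(H + 2, Wd + 2, C))
  padded[2:(H + 1), 2:(Wd + 1), ] <- x
  cols <- matrix(0, H * Wd, 9 * C)
  k <- 1L
  for (c in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        cols[, k] <- as.vector(padded[(1 + di):(H + di), (1 + dj):(Wd + dj), c])
        k <- k + 1L
      }
    }
  }
  out <- cols %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, dim = c(H, Wd, ncol(W))), cols = cols,
       in_dim = c(H, Wd, C))
}

# dout: H x W x F array; returns gradients and dx (H x W x C)
conv_backward <- function(cache, W, dout) {
  H <- cache$in_dim[1]; Wd <- cache$in_dim[2]; C <- cache$in_dim[3]
  dmat <- matrix(dout, H * Wd, dim(dout)[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  dpad <- array(0, dim = c(H + 2, Wd + 2, C))
  k <- 1L
  for (c in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        dpad[(1 + di):(H + di), (1 + dj):(Wd + dj), c] <-
          dpad[(1 + di):(H + di), (1 + dj):(Wd + dj), c] +
          matrix(dcols[, k], H, Wd)
        k <- k + 1L
      }
    }
  }
  list(dW = dW, db = db, dx = dpad[2:(H + 1), 2:(Wd + 1), , drop = FALSE])
}

# --- 2x2 mean pooling (stride 2; H, W even) --------------------------------

pool_forward <- function(x) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  o <- seq(1, H, by = 2); e <- seq(2, H, by = 2)
  oc <- seq(1, Wd, by = 2); ec <- seq(2, Wd, by = 2)
  (x[o, oc, , drop = FALSE] + x[e, oc, , drop = FALSE] +
     x[o, ec, , drop = FALSE] + x[e, ec, , drop = FALSE]) / 4
}

pool_backward <- function(dout, in_dim) {
  H <- in_dim[1]; Wd <- in_dim[2]
  dx <- array(0, dim = in_dim)
  o <- seq(1, H, by = 2); e <- seq(2, H, by = 2)
  oc <- seq(1, Wd, by = 2); ec <- seq(2, Wd, by = 2)
  g <- dout / 4
  dx[o, oc, ] <- g; dx[e, oc, ] <- g; dx[o, ec, ] <- g; dx[e, ec, ] <- g
  dx
}

# --- backbone (stacked conv-relu-pool blocks) ------------------------------

# One forward pass through the backbone; keep_from: earliest block whose
# backward pass is needed (caches are stored from there on; 0 = none).
backbone_forward <- function(backbone, img, keep_from = 0L) {
  x <- array(img, dim = c(dim(img)[1], dim(img)[2], 1))
  caches <- vector("list", length(backbone$blocks))
  for (k in seq_along(backbone$blocks)) {
    blk <- backbone$blocks[[k]]
    cf <- conv_forward(x, blk$W, blk$b)
    a <- pmax(cf$out, 0)
    p <- pool_forward(a)
    if (keep_from > 0L && k >= keep_from) {
      caches[[k]] <- list(conv = cf, pre_relu = cf$out, pre_pool_dim = dim(a))
    }
    x <- p
  }
  list(features = as.vector(x), caches = caches, out_dim = dim(x))
}

# Backward from feature gradient down to (and including) block `down_to`.
backbone_backward <- function(backbone, fwd, dfeat, down_to) {
  dx <- array(dfeat, dim = fwd$out_dim)
  grads <- vector("list", length(backbone$blocks))
  for (k in rev(seq_along(backbone$blocks))) {
    if (k < down_to) break
    cache <- fwd$caches[[k]]
    da <- pool_backward(dx, cache$pre_pool_dim)
    da <- da * (cache$pre_relu > 0)
    cb <- conv_backward(cache$conv, backbone$blocks[[k]]$W, da)
    grads[[k]] <- list(dW = cb$dW, db = cb$db)
    dx <- cb$dx
  }
  grads
}

# --- dense head ------------------------------------------------------------

# X: B x in matrix. Returns activations needed for backward.
head_forward <- function(head, X, dropout_masks = NULL) {
  acts <- list(x0 = X)
  h <- X
  for (i in 1:3) {
    z <- sweep(h %*% head$dense[[i]]$W, 2, head$dense[[i]]$b, `+`)
    a <- pmax(z, 0)
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[i]]
    acts[[paste0("z", i)]] <- z
    acts[[paste0("a", i)]] <- a
    h <- a
  }
  z4 <- sweep(h %*% head$dense[[4]]$W, 2, head$dense[[4]]$b, `+`)
  p <- 1 / (1 + exp(-z4))
  acts$z4 <- z4
  acts$p <- p
  acts
}

# dz4: B x 1 gradient at the output pre-activation. Returns per-layer
# gradients and the gradient w.r.t. the input features (for fine-tuning).
head_backward <- function(head, acts, dz4, dropout_masks = NULL) {
  grads <- list(dense = vector("list", 4))
  grads$dense[[4]] <- list(dW = crossprod(acts$a3, dz4), db = colSums(dz4))
  dh <- dz4 %*% t(head$dense[[4]]$W)
  for (i in 3:1) {
    if (!is.null(dropout_masks)) dh <- dh * dropout_masks[[i]]
    dh <- dh * (acts[[paste0("z", i)]] > 0)
    xin <- if (i == 1) acts$x0 else acts[[paste0("a", i - 1)]]
    grads$dense[[i]] <- list(dW = crossprod(xin, dh), db = colSums(dh))
    dh <- dh %*% t(head$dense[[i]]$W)
  }
  list(grads = grads, dx = dh)
}

# --- parameter initialization and Adam -------------------------------------

he_init <- function(n_in, n_out, rng) {
  matrix(rng_rnorm(rng, n_in * n_out) * sqrt(2 / n_in), n_in, n_out)
}

init_head_params <- function(spec, n_features, rng) {
  units <- spec$dense_units
  sizes <- rbind(c(n_features, units[1]), c(units[1], units[2]),
                 c(units[2], units[3]), c(units[3], 1))
  dense <- lapply(seq_len(4), function(i) {
    list(W = he_init(sizes[i, 1], sizes[i, 2], rng),
         b = numeric(sizes[i, 2]))
  })
  list(dense = dense, dropout_rates = spec$dropout_rates)
}

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(state, key, param, grad, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- get0(paste0(key, ".m"), envir = state, ifnotfound = param * 0)
  v <- get0(paste0(key, ".v"), envir = state, ifnotfound = param * 0)
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  assign(paste0(key, ".m"), m, envir = state)
  assign(paste0(key, ".v"), v, envir = state)
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  param - lr * mh / (sqrt(vh) + eps)
}
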