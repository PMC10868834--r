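#' @useDynLib rnadistgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network layer used by the VQ-VAE, generator and score model.
# Layers are environments exposing forward(x, train)/backward(dy); tensors are
# (H, W, C, N) arrays.  Convolutions run through the compiled im2col kernels.
# ---------------------------------------------------------------------------

nn_conv <- function(k, c_in, c_out, dilation = 1L, input_layer = FALSE) {
  self <- new.env(parent = emptyenv())
  self$kind <- "conv"
  self$k <- as.integer(k); self$dilation <- as.integer(dilation)
  self$c_in <- c_in; self$c_out <- c_out
  self$input_layer <- isTRUE(input_layer)  # skip dx for network inputs
  fan_in <- k * k * c_in
  self$params <- list(
    w = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
               fan_in, c_out),
    b = numeric(c_out))
  self$grads <- list(w = NULL, b = NULL)
  self$forward <- function(x, train = TRUE) {
    if (train) self$x <- x
    cpp_conv2d_forward(x, self$params$w, self$params$b, self$k, self$dilation)
  }
  self$backward <- function(dy) {
    g <- cpp_conv2d_backward(self$x, self$params$w, dy, self$k, self$dilation,
                             !self$input_layer)
    self$grads$w <- matrix(g$dw, nrow(self$params$w), self$c_out)
    self$grads$b <- g$db
    g$dx
  }
  self
}

nn_batchnorm <- function(c, momentum = 0.9, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$kind <- "batchnorm"
  self$params <- list(gamma = rep(1, c), beta = numeric(c))
  self$grads <- list(gamma = NULL, beta = NULL)
  self$run_mean <- numeric(c); self$run_var <- rep(1, c)
  # stats over batch and spatial dims; data stays in (H*W, C*N) layout with
  # channel fastest in the column index, avoiding aperm copies
  chan_stat <- function(colsums, C, N) rowSums(matrix(colsums, C, N))
  self$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
    xm <- x; dim(xm) <- c(HW, C * N)
    m <- HW * N
    if (train) {
      s1 <- chan_stat(.colSums(xm, HW, C * N), C, N)
      s2 <- chan_stat(.colSums(xm^2, HW, C * N), C, N)
      mu <- s1 / m
      v <- s2 / m - mu^2
      self$run_mean <- momentum * self$run_mean + (1 - momentum) * mu
      self$run_var <- momentum * self$run_var + (1 - momentum) * v
    } else {
      mu <- self$run_mean; v <- self$run_var
    }
    istd <- 1 / sqrt(v + eps)
    cscale <- rep(istd, N); cshift <- rep(-mu * istd, N)
    xhat <- sweep(xm, 2, cscale, "*")
    xhat <- sweep(xhat, 2, cshift, "+")
    y <- sweep(xhat, 2, rep(self$params$gamma, N), "*")
    y <- sweep(y, 2, rep(self$params$beta, N), "+")
    if (train) { self$xhat <- xhat; self$istd <- istd; self$dims <- d }
    dim(y) <- d
    y
  }
  self$backward <- function(dy) {
    d <- self$dims; C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
    dym <- dy; dim(dym) <- c(HW, C * N)
    m <- HW * N
    self$grads$gamma <- chan_stat(.colSums(dym * self$xhat, HW, C * N), C, N)
    self$grads$beta <- chan_stat(.colSums(dym, HW, C * N), C, N)
    dxh <- sweep(dym, 2, rep(self$params$gamma, N), "*")
    s1 <- chan_stat(.colSums(dxh, HW, C * N), C, N)
    s2 <- chan_stat(.colSums(dxh * self$xhat, HW, C * N), C, N)
    dxm <- dxh - sweep(self$xhat, 2, rep(s2 / m, N), "*")
    dxm <- sweep(dxm, 2, rep(s1 / m, N), "-")
    dxm <- sweep(dxm, 2, rep(self$istd, N), "*")
    dim(dxm) <- d
    dxm
  }
  self
}

nn_act <- function(type = c("relu", "elu")) {
  type <- match.arg(type)
  self <- new.env(parent = emptyenv())
  self$kind <- type
  self$forward <- function(x, train = TRUE) {
    if (type == "relu") y <- x * (x > 0)
    else { y <- x; neg <- x <= 0; y[neg] <- expm1(x[neg]) }
    if (train) self$y <- y
    y
  }
  self$backward <- function(dy) {
    if (type == "relu") dy * (self$y > 0)
    else {
      g <- dy; neg <- self$y <= 0
      g[neg] <- dy[neg] * (self$y[neg] + 1)
      g
    }
  }
  self
}

nn_seq <- function(...) {
  self <- new.env(parent = emptyenv())
  self$kind <- "seq"
  self$layers <- list(...)
  self$forward <- function(x, train = TRUE) {
    for (l in self$layers) x <- l$forward(x, train)
    x
  }
  self$backward <- function(dy) {
    for (l in rev(self$layers)) dy <- l$backward(dy)
    dy
  }
  self
}

# Residual block "Block = 2x[Batchnorm, ReLU, Conv]" with identity skip, or a
# 1x1 projection when the channel count changes across the block.
nn_resblock <- function(c_in, k1, c1, k2, c2, act = "relu",
                        dilation2 = 1L) {
  self <- new.env(parent = emptyenv())
  self$kind <- "resblock"
  self$body <- nn_seq(
    nn_batchnorm(c_in), nn_act(act), nn_conv(k1, c_in, c1),
    nn_batchnorm(c1), nn_act(act), nn_conv(k2, c1, c2, dilation = dilation2))
  self$proj <- if (c_in != c2) nn_conv(1, c_in, c2) else NULL
  self$layers <- c(list(self$body), if (!is.null(self$proj)) list(self$proj))
  self$forward <- function(x, train = TRUE) {
    s <- if (is.null(self$proj)) x else self$proj$forward(x, train)
    s + self$body$forward(x, train)
  }
  self$backward <- function(dy) {
    dx <- self$body$backward(dy)
    dx + if (is.null(self$proj)) dy else self$proj$backward(dy)
  }
  self
}

# Generator/score-model block: two stacked sub-residuals, the second one
# closing over a dilated convolution.
nn_resblock2 <- function(c, k = 3L, act = "elu", dilation = 2L) {
  self <- new.env(parent = emptyenv())
  self$kind <- "resblock2"
  self$sub1 <- nn_seq(nn_batchnorm(c), nn_act(act), nn_conv(k, c, c),
                      nn_batchnorm(c), nn_act(act), nn_conv(k, c, c))
  self$sub2 <- nn_seq(nn_batchnorm(c), nn_act(act), nn_conv(k, c, c),
                      nn_batchnorm(c), nn_act(act),
                      nn_conv(k, c, c, dilation = dilation))
  self$layers <- list(self$sub1, self$sub2)
  self$forward <- function(x, train = TRUE) {
    h <- x + self$sub1$forward(x, train)
    h + self$sub2$forward(h, train)
  }
  self$backward <- function(dy) {
    dh <- dy + self$sub2$backward(dy)
    dh + self$sub1$backward(dh)
  }
  self
}

# --- parameter bookkeeping --------------------------------------------------

nn_leaves <- function(layer) {
  if (!is.null(layer$layers)) {
    unlist(lapply(layer$layers, nn_leaves), recursive = FALSE)
  } else if (!is.null(layer$params)) list(layer) else list()
}

nn_n_params <- function(net) {
  sum(vapply(nn_leaves(net),
             function(l) sum(vapply(l$params, length, 1L)), 1))
}

nn_adam_init <- function(net) {
  lapply(nn_leaves(net), function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

#' @noRd
nn_adam_step <- function(net, state, t, lr, beta1 = 0.9, beta2 = 0.997,
                         eps = 1e-8, weight_decay = 0) {
  leaves <- nn_leaves(net)
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      # L2 regularization on conv weights only (not biases / norm params)
      if (weight_decay > 0 && nm == "w") g <- g + weight_decay * l$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  state
}

# Serializable snapshot of all parameters (environments do not copy on save).
nn_get_params <- function(net) lapply(nn_leaves(net), function(l)
  list(params = l$params, run_mean = l$run_mean, run_var = l$run_var))

nn_set_params <- function(net, snap) {
  leaves <- nn_leaves(net)
  stopifnot(length(leaves) == length(snap))
  for (i in seq_along(leaves)) {
    leaves[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      leaves[[i]]$run_mean <- snap[[i]]$run_mean
      leaves[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(net)
}

# learning-rate schedule: linear warmup then cosine decay to zero
lr_schedule <- function(step, base_lr, warmup, total) {
  if (step <= warmup && warmup > 0) return(base_lr * step / warmup)
  frac <- (step - warmup) / max(1, total - warmup)
  base_lr * 0.5 * (1 + cos(pi * min(1, frac)))
}
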