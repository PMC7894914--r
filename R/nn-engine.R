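# Minimal feed-forward/recurrent network engine backing the model zoo.
# Layouts: image activations (H, W, C, N); sequence activations (T, F, N);
# dense activations N x D matrices. Forward caches what backward needs;
# backward returns parameter gradients plus the gradient with respect to
# the network input (used for saliency).

BN_EPS <- 1e-3
# Running-statistics momentum. With only a few hundred minibatch updates
# (small datasets, early stopping), a 0.99 momentum leaves the inference
# statistics dominated by their initialisation; 0.9 converges to the batch
# statistics within a few epochs at these problem sizes.
BN_MOMENTUM <- 0.9

nn_shapes <- function(layers, input_shape) {
  shape <- input_shape
  out <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    shape <- switch(l$type,
      conv2d = c(shape[1], shape[2], l$filters),
      conv1d = c(shape[1], l$filters),
      pool2d = c(shape[1] %/% l$size[1], shape[2] %/% l$size[2], shape[3]),
      pool1d = c(shape[1] %/% l$size, shape[2]),
      dropout = shape,
      flatten = prod(shape),
      dense = l$units,
      batchnorm = shape,
      lstm = if (isTRUE(l$return_seq)) c(shape[1], l$units) else l$units,
      abort(paste("unknown layer type", l$type))
    )
    out[[li]] <- shape
  }
  out
}

nn_init_params <- function(layers, input_shape, seed) {
  old <- seed_guard(seed)
  on.exit(old(), add = TRUE)
  shapes <- nn_shapes(layers, input_shape)
  params <- list()
  shape <- input_shape
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    key <- function(p) paste0("L", li, ".", p)
    if (l$type == "conv2d") {
      fan_in <- l$kernel^2 * shape[3]
      params[[key("W")]] <- array(rnorm(l$kernel^2 * shape[3] * l$filters,
                                        0, sqrt(2 / fan_in)),
                                  dim = c(l$kernel, l$kernel, shape[3], l$filters))
      params[[key("b")]] <- numeric(l$filters)
    } else if (l$type == "conv1d") {
      fan_in <- l$kernel * shape[2]
      params[[key("W")]] <- array(rnorm(l$kernel * shape[2] * l$filters,
                                        0, sqrt(2 / fan_in)),
                                  dim = c(l$kernel, 1L, shape[2], l$filters))
      params[[key("b")]] <- numeric(l$filters)
    } else if (l$type == "dense") {
      d_in <- shape[1]
      sd <- if (identical(l$activation, "relu")) sqrt(2 / d_in)
            else sqrt(2 / (d_in + l$units))
      params[[key("W")]] <- matrix(rnorm(d_in * l$units, 0, sd), d_in, l$units)
      params[[key("b")]] <- numeric(l$units)
    } else if (l$type == "batchnorm") {
      params[[key("gamma")]] <- rep(1, shape[1])
      params[[key("beta")]] <- numeric(shape[1])
    } else if (l$type == "lstm") {
      f_in <- shape[2]
      u <- l$units
      params[[key("Wx")]] <- matrix(rnorm(f_in * 4 * u, 0,
                                          sqrt(2 / (f_in + 4 * u))), f_in, 4 * u)
      params[[key("Wh")]] <- matrix(rnorm(u * 4 * u, 0, sqrt(2 / (5 * u))),
                                    u, 4 * u)
      b <- numeric(4 * u)
      b[(u + 1):(2 * u)] <- 1  # forget-gate bias starts open
      params[[key("b")]] <- b
    }
    shape <- shapes[[li]]
  }
  params
}

nn_init_state <- function(layers, input_shape) {
  shapes <- nn_shapes(layers, input_shape)
  state <- list()
  shape <- input_shape
  for (li in seq_along(layers)) {
    if (layers[[li]]$type == "batchnorm") {
      state[[paste0("L", li, ".mean")]] <- numeric(shape[1])
      state[[paste0("L", li, ".var")]] <- rep(1, shape[1])
    }
    shape <- shapes[[li]]
  }
  state
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass. `x`: input batch with trailing sample dimension (or N x D
# matrix after flatten). Returns logits plus per-layer caches and (in
# training mode) updated batch-norm running statistics.
nn_forward <- function(model, x, training = FALSE) {
  layers <- model$spec$layers
  params <- model$params
  state <- model$state
  caches <- vector("list", length(layers))
  cur <- x
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    key <- function(p) paste0("L", li, ".", p)
    if (l$type %in% c("conv2d", "conv1d")) {
      xd <- dim(cur)
      if (l$type == "conv1d") dim(cur) <- c(xd[1], 1L, xd[2], xd[3])
      y <- nn_conv2d_fwd(cur, dim(cur), params[[key("W")]],
                         dim(params[[key("W")]]), params[[key("b")]])
      if (identical(l$activation, "relu")) y <- relu_fwd(y)
      if (l$type == "conv1d") {
        dim(cur) <- xd
        dim(y) <- c(dim(y)[1], dim(y)[3], dim(y)[4])
      }
      caches[[li]] <- list(x = cur, y = y)
      cur <- y
    } else if (l$type %in% c("pool2d", "pool1d")) {
      xd <- dim(cur)
      size <- if (l$type == "pool1d") c(l$size, 1L) else l$size
      if (l$type == "pool1d") dim(cur) <- c(xd[1], 1L, xd[2], xd[3])
      r <- nn_pool2d_fwd(cur, dim(cur), size[1], size[2],
                         as.integer(identical(l$op, "max")))
      y <- r$y
      caches[[li]] <- list(xd = dim(cur), argmax = r$argmax, seq = l$type == "pool1d")
      if (l$type == "pool1d") {
        dim(cur) <- xd
        dim(y) <- c(dim(y)[1], dim(y)[3], dim(y)[4])
      }
      cur <- y
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        keep <- runif(length(cur)) >= l$rate
        y <- cur * keep / (1 - l$rate)
        if (!is.null(dim(cur))) dim(y) <- dim(cur)
        caches[[li]] <- list(keep = keep, rate = l$rate)
        cur <- y
      } else {
        caches[[li]] <- list(keep = NULL)
      }
    } else if (l$type == "flatten") {
      xd <- dim(cur)
      n <- xd[length(xd)]
      caches[[li]] <- list(xd = xd)
      cur <- t(matrix(cur, prod(xd[-length(xd)]), n))
    } else if (l$type == "dense") {
      pre <- cur %*% params[[key("W")]]
      pre <- sweep(pre, 2, params[[key("b")]], "+")
      y <- if (identical(l$activation, "relu")) relu_fwd(pre) else pre
      caches[[li]] <- list(x = cur, y = y)
      cur <- y
    } else if (l$type == "batchnorm") {
      gamma <- params[[key("gamma")]]
      beta <- params[[key("beta")]]
      if (training) {
        mu <- colMeans(cur)
        v <- colMeans(cur^2) - mu^2
        state[[key("mean")]] <- BN_MOMENTUM * state[[key("mean")]] +
          (1 - BN_MOMENTUM) * mu
        state[[key("var")]] <- BN_MOMENTUM * state[[key("var")]] +
          (1 - BN_MOMENTUM) * v
      } else {
        mu <- state[[key("mean")]]
        v <- state[[key("var")]]
      }
      istd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(cur, 2, mu, "-"), 2, istd, "*")
      y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
      caches[[li]] <- list(xhat = xhat, istd = istd, training = training)
      cur <- y
    } else if (l$type == "lstm") {
      xd <- dim(cur)
      r <- nn_lstm_fwd(cur, xd, params[[key("Wx")]], params[[key("Wh")]],
                       params[[key("b")]])
      caches[[li]] <- list(x = cur, fwd = r, return_seq = isTRUE(l$return_seq))
      if (isTRUE(l$return_seq)) {
        cur <- r$h
      } else {
        h <- r$h  # (T, U, N)
        cur <- t(matrix(h[dim(h)[1], , ], dim(h)[2], dim(h)[3]))
      }
    }
  }
  list(out = cur, caches = caches, state = state)
}

# Backward pass from d(out) (N x K matrix of gradients on the logits).
# Returns named parameter gradients and the input gradient.
nn_backward <- function(model, caches, dout) {
  layers <- model$spec$layers
  params <- model$params
  grads <- list()
  dy <- dout
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    key <- function(p) paste0("L", li, ".", p)
    cc <- caches[[li]]
    if (l$type %in% c("conv2d", "conv1d")) {
      if (identical(l$activation, "relu")) dy <- dy * (cc$y > 0)
      xd <- dim(cc$x)
      x4 <- cc$x
      if (l$type == "conv1d") {
        dim(x4) <- c(xd[1], 1L, xd[2], xd[3])
        dim(dy) <- c(dim(dy)[1], 1L, dim(dy)[2], dim(dy)[3])
      }
      r <- nn_conv2d_bwd(x4, dim(x4), params[[key("W")]],
                         dim(params[[key("W")]]), dy)
      grads[[key("W")]] <- r$dW
      grads[[key("b")]] <- r$db
      dy <- r$dx
      if (l$type == "conv1d") dim(dy) <- xd
    } else if (l$type %in% c("pool2d", "pool1d")) {
      size <- if (l$type == "pool1d") c(l$size, 1L) else l$size
      if (l$type == "pool1d") {
        dd <- dim(dy)
        dim(dy) <- c(dd[1], 1L, dd[2], dd[3])
      }
      dy <- nn_pool2d_bwd(dy, cc$xd, size[1], size[2],
                          as.integer(identical(l$op, "max")), cc$argmax)
      if (l$type == "pool1d") dim(dy) <- c(cc$xd[1], cc$xd[3], cc$xd[4])
    } else if (l$type == "dropout") {
      if (!is.null(cc$keep)) {
        dd <- dim(dy)
        dy <- dy * cc$keep / (1 - cc$rate)
        if (!is.null(dd)) dim(dy) <- dd
      }
    } else if (l$type == "flatten") {
      dy <- array(t(dy), dim = cc$xd)
    } else if (l$type == "dense") {
      if (identical(l$activation, "relu")) dy <- dy * (cc$y > 0)
      grads[[key("W")]] <- crossprod(cc$x, dy)
      grads[[key("b")]] <- colSums(dy)
      dy <- tcrossprod(dy, params[[key("W")]])
    } else if (l$type == "batchnorm") {
      gamma <- params[[key("gamma")]]
      xhat <- cc$xhat
      grads[[key("gamma")]] <- colSums(dy * xhat)
      grads[[key("beta")]] <- colSums(dy)
      dxhat <- sweep(dy, 2, gamma, "*")
      if (cc$training) {
        n <- nrow(dy)
        dy <- sweep(dxhat -
                      matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                      sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
                    2, cc$istd, "*")
      } else {
        dy <- sweep(dxhat, 2, cc$istd, "*")
      }
    } else if (l$type == "lstm") {
      xd <- dim(cc$x)
      u <- l$units
      tlen <- xd[1]
      n <- xd[3]
      if (cc$return_seq) {
        dh <- dy
      } else {
        dh <- array(0, dim = c(tlen, u, n))
        dh[tlen, , ] <- t(dy)
      }
      r <- nn_lstm_bwd(cc$x, xd, params[[key("Wx")]], params[[key("Wh")]],
                       cc$fwd$gates, cc$fwd$c, cc$fwd$h, dh)
      grads[[key("Wx")]] <- r$dWx
      grads[[key("Wh")]] <- r$dWh
      grads[[key("b")]] <- r$db
      dy <- r$dx
    }
  }
  list(grads = grads, dx = dy)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ADAM with the standard published defaults (beta1 = 0.9, beta2 = 0.999,
# eps = 1e-8). The moment buffers and parameter copies are owned by the
# training loop, so the C++ kernel updates them in place; `deep_copy`
# severs sharing before and after (snapshots, returned model).
adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  nn_adam_update(params, opt$m, opt$v, grads, lr, beta1, beta2, opt$t, eps)
  list(opt = opt, params = params)
}

deep_copy <- function(params) lapply(params, function(p) p + 0)

# Index a batch out of an array whose last dimension is the sample axis.
batch_slice <- function(x, idx) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 4L) x[, , , idx, drop = FALSE]
  else if (nd == 3L) x[, , idx, drop = FALSE]
  else x[idx, , drop = FALSE]
}

n_samples <- function(x) dim(x)[length(dim(x))]
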