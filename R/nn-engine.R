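# Minimal feed-forward / convolutional network engine.
#
# Data conventions: dense activations are (features x batch) matrices;
# convolutional activations are (h, w, channels, batch) arrays. Convolution
# is "valid" with stride 1, implemented as im2col + one matrix product per
# batch; max-pooling is non-overlapping with floor cropping. Training uses
# Adam on a binary cross-entropy loss with sigmoid output. Everything runs
# on base R + BLAS (plus one sparse scatter operator for the conv input
# gradient), which is fast enough for the desk-scale images this package
# targets.

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- layer constructors --------------------------------------------------

# He-initialised weights; RNG state is the caller's responsibility
init_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

init_conv <- function(k, ch_in, n_filters, in_h, in_w) {
  if (k > in_h || k > in_w) {
    stop(sprintf("kernel size %d exceeds input map %d x %d", k, in_h, in_w),
         call. = FALSE)
  }
  oh <- in_h - k + 1L
  ow <- in_w - k + 1L
  K <- k * k * ch_in
  # base_idx[K, oh*ow]: linear index into an (h, w, ch) array for each
  # kernel tap at each output position (output positions i fastest)
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))
  tap <- expand.grid(di = seq_len(k), dj = seq_len(k), ci = seq_len(ch_in))
  base_idx <- outer(seq_len(K), seq_len(oh * ow), function(t, p) {
    (tap$ci[t] - 1L) * in_h * in_w +
      (pos$j[p] + tap$dj[t] - 2L) * in_h +
      (pos$i[p] + tap$di[t] - 1L)
  })
  storage.mode(base_idx) <- "integer"
  # sparse scatter operator for the input gradient: (K*oh*ow) -> (h*w*ch)
  scatter <- Matrix::sparseMatrix(
    i = seq_len(K * oh * ow), j = as.vector(base_idx),
    x = 1, dims = c(K * oh * ow, in_h * in_w * ch_in)
  )
  list(type = "conv", k = k, ch_in = ch_in, n_filters = n_filters,
       in_h = in_h, in_w = in_w, oh = oh, ow = ow,
       base_idx = base_idx, scatter = scatter,
       W = matrix(stats::rnorm(n_filters * K, sd = sqrt(2 / K)), n_filters, K),
       b = numeric(n_filters))
}

# ---- forward / backward --------------------------------------------------

im2col_batch <- function(x, layer) {
  d <- dim(x)
  B <- d[4]
  P <- layer$oh * layer$ow
  K <- nrow(layer$base_idx)
  xf <- as.vector(x)
  Xc <- matrix(0, K, P * B)
  stride <- d[1] * d[2] * d[3]
  for (b in seq_len(B)) {
    Xc[, ((b - 1L) * P + 1L):(b * P)] <- xf[layer$base_idx + (b - 1L) * stride]
  }
  Xc
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      B <- dim(x)[4]
      Xc <- im2col_batch(x, layer)
      out <- layer$W %*% Xc + layer$b
      dim(out) <- c(layer$n_filters, layer$oh, layer$ow, B)
      out <- aperm(out, c(2, 3, 1, 4))
      list(out = out, cache = list(Xc = Xc, B = B, first = FALSE))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask)
    },
    pool = {
      s <- layer$s
      d <- dim(x)
      oh <- (d[1] %/% s) * s
      ow <- (d[2] %/% s) * s
      ri <- lapply(seq_len(s), function(di) seq(di, oh, by = s))
      ci <- lapply(seq_len(s), function(dj) seq(dj, ow, by = s))
      out <- NULL
      for (di in seq_len(s)) for (dj in seq_len(s)) {
        sl <- x[ri[[di]], ci[[dj]], , , drop = FALSE]
        out <- if (is.null(out)) sl else pmax(out, sl)
      }
      list(out = out, cache = list(x = x, out = out, oh = oh, ow = ow))
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(prod(d[1:3]), d[4])
      list(out = out, cache = d)
    },
    dense = {
      list(out = layer$W %*% x + layer$b, cache = x)
    },
    batchnorm = {
      eps <- 1e-5
      if (training) {
        mu <- rowMeans(x)
        v <- rowMeans((x - mu)^2)
        layer$running_mean <- 0.9 * layer$running_mean + 0.1 * mu
        layer$running_var <- 0.9 * layer$running_var + 0.1 * v
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
      }
      inv <- 1 / sqrt(v + eps)
      xhat <- (x - mu) * inv
      list(out = layer$gamma * xhat + layer$beta,
           cache = list(xhat = xhat, inv = inv, x = x, mu = mu),
           layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = mask)
      } else {
        list(out = x, cache = NULL)
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dout, cache, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      B <- cache$B
      P <- layer$oh * layer$ow
      dO <- aperm(dout, c(3, 1, 2, 4))
      dim(dO) <- c(layer$n_filters, P * B)
      grads <- list(W = tcrossprod(dO, cache$Xc), b = rowSums(dO))
      dx <- NULL
      if (need_dx) {
        dXc <- crossprod(layer$W, dO)
        dim(dXc) <- c(nrow(layer$base_idx) * P, B)
        dxf <- as.matrix(Matrix::crossprod(layer$scatter, dXc))
        dx <- array(dxf, dim = c(layer$in_h, layer$in_w, layer$ch_in, B))
      }
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dout * cache, grads = NULL),
    pool = {
      s <- layer$s
      x <- cache$x
      d <- dim(x)
      dx <- array(0, d)
      assigned <- array(FALSE, dim(cache$out))
      for (di in seq_len(s)) for (dj in seq_len(s)) {
        rr <- seq(di, cache$oh, by = s)
        cc <- seq(dj, cache$ow, by = s)
        sl <- x[rr, cc, , , drop = FALSE]
        hit <- (sl == cache$out) & !assigned
        assigned <- assigned | hit
        dx[rr, cc, , ] <- dx[rr, cc, , , drop = FALSE] + dout * hit
      }
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    dense = {
      grads <- list(W = tcrossprod(dout, cache), b = rowSums(dout))
      dx <- if (need_dx) crossprod(layer$W, dout) else NULL
      list(dx = dx, grads = grads)
    },
    batchnorm = {
      B <- ncol(dout)
      xhat <- cache$xhat
      inv <- cache$inv
      dgamma <- rowSums(dout * xhat)
      dbeta <- rowSums(dout)
      dxhat <- dout * layer$gamma
      dx <- inv / B * (B * dxhat - rowSums(dxhat) -
                         xhat * rowSums(dxhat * xhat))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    }
  )
}

# ---- training ------------------------------------------------------------

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x, training)
    if (!is.null(fw$layer)) layers[[i]] <- fw$layer # batchnorm running stats
    caches[[i]] <- fw$cache
    x <- fw$out
  }
  list(out = x, caches = caches, layers = layers)
}

adam_update <- function(layer, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state[[nm]])) state[[nm]] <- list(m = g * 0, v = g * 0)
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    layer[[nm]] <- layer[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(layer = layer, state = state)
}

# one optimisation run over (x, y); x is (features x n) or (h, w, ch, n)
nn_train <- function(layers, states, x, y, epochs, lr, batch_size, seed,
                     step0 = 0L) {
  if (epochs == 0) return(list(layers = layers, states = states,
                               losses = numeric(0), step = step0))
  is_img <- length(dim(x)) == 4
  n <- if (is_img) dim(x)[4] else ncol(x)
  set.seed(seed)
  t <- step0
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample(n)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      xb <- if (is_img) x[, , , idx, drop = FALSE] else x[, idx, drop = FALSE]
      yb <- y[idx]
      fw <- nn_forward(layers, xb, training = TRUE)
      layers <- fw$layers
      p <- sigmoid(as.vector(fw$out))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - mean(yb * log(p) + (1 - yb) * log(1 - p))
      nb <- nb + 1
      dz <- matrix((p - yb) / length(yb), nrow = 1)
      t <- t + 1L
      dout <- dz
      for (i in rev(seq_along(layers))) {
        bw <- layer_backward(layers[[i]], dout, fw$caches[[i]],
                             need_dx = i > 1)
        if (!is.null(bw$grads)) {
          upd <- adam_update(layers[[i]], bw$grads, states[[i]], lr, t)
          layers[[i]] <- upd$layer
          states[[i]] <- upd$state
        }
        dout <- bw$dx
      }
    }
    losses[ep] <- ep_loss / nb
  }
  list(layers = layers, states = states, losses = losses, step = t)
}

nn_predict <- function(layers, x) {
  as.vector(sigmoid(nn_forward(layers, x, training = FALSE)$out))
}

# parameter count of a layer stack
nn_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    length(l[["W"]]) + length(l[["b"]]) +
      length(l[["gamma"]]) + length(l[["beta"]])
  }, numeric(1)))
}
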