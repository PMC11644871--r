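# Minimal dense/convolutional network engine used by the segmentation
# module. Tensors are channel-first arrays (C, H, W, B): with channels
# fastest, the im2col matrix of a stride-1 convolution is assembled from
# k*k contiguous range-subset copies (no element gathers, no transposes),
# and both the forward product and the weight gradient are single BLAS
# calls. Input gradients are computed as a transposed convolution so both
# directions share the same fast path. Everything is deterministic given
# the RNG state.
#
# Weight layout: W is (F x C*k*k); column index = c + C*(ki + k*kj)
# (channel fastest, then kernel row, then kernel column).

im2col <- function(X, k, pad) {
  d <- dim(X)
  list(cols = cs_im2col(X, as.integer(d), as.integer(k), as.integer(pad)),
       oh = d[2] + 2L * pad - k + 1L, ow = d[3] + 2L * pad - k + 1L)
}

# Forward convolution. Returns the output tensor plus (optionally) the
# im2col matrix for the weight gradient.
conv_fwd <- function(X, W, b = NULL, k, pad = 0L, keep_cols = FALSE) {
  d <- dim(X)
  if (k == 1L && pad == 0L) {
    cols <- X
    dim(cols) <- c(d[1], d[2] * d[3] * d[4])
    oh <- d[2]; ow <- d[3]
  } else {
    ic <- im2col(X, k, pad)
    cols <- ic$cols; oh <- ic$oh; ow <- ic$ow
  }
  Ymat <- W %*% cols
  if (!is.null(b)) Ymat <- Ymat + b
  Y <- Ymat
  dim(Y) <- c(nrow(W), oh, ow, d[4])
  list(Y = Y, cols = if (keep_cols) cols else NULL,
       in_dim = d, k = k, pad = pad)
}

# Gradients of a convolution. Needs the forward cache (with cols kept).
conv_bwd <- function(dY, W, cache) {
  k <- cache$k; pad <- cache$pad
  d <- dim(dY); Fch <- d[1]
  dYmat <- dY
  dim(dYmat) <- c(Fch, d[2] * d[3] * d[4])
  dW <- tcrossprod(dYmat, cache$cols)
  db <- rowSums(dYmat)
  # input gradient: full (transposed) convolution with the flipped kernel
  C <- cache$in_dim[1]
  dX <- conv_fwd(dY, flip_weights(W, k, C), b = NULL, k = k,
                 pad = k - 1L - pad)$Y
  list(dW = dW, db = db, dX = dX)
}

# Rearrange (F x C*k*k) weights into the (C x F*k*k) matrix of the
# transposed convolution (kernel flipped in both spatial dimensions).
flip_weights <- function(W, k, C) {
  Fch <- nrow(W)
  Wa <- array(W, c(Fch, C, k, k))
  Wa <- Wa[, , k:1, k:1, drop = FALSE]
  Wt <- aperm(Wa, c(2, 1, 3, 4))
  dim(Wt) <- c(C, Fch * k * k)
  Wt
}

# Batch normalization over a channel-first tensor: statistics per channel
# across all spatial positions and the batch. `stats = NULL` uses batch
# statistics (training mode); otherwise the supplied running statistics
# (inference). With channels fastest, every op is a column-recycled
# vector operation.
bn_fwd <- function(X, g, b, stats = NULL, eps = 1e-5) {
  d <- dim(X); C <- d[1]
  m <- X; dim(m) <- c(C, length(X) / C)
  if (is.null(stats)) {
    mu <- rowMeans(m)
    v <- pmax(rowMeans(m * m) - mu * mu, 0)
  } else {
    mu <- stats$mean; v <- stats$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * inv
  y <- g * xhat + b
  dim(y) <- d
  list(Y = y, xhat = xhat, inv = inv, batch_mean = mu, batch_var = v,
       in_dim = d)
}

bn_bwd <- function(dY, g, cache) {
  d <- cache$in_dim; C <- d[1]
  dm <- dY; dim(dm) <- c(C, length(dY) / C)
  n <- ncol(dm)
  dg <- rowSums(dm * cache$xhat)
  db <- rowSums(dm)
  dxhat <- dm * g
  t1 <- rowSums(dxhat)
  t2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$inv / n) * (n * dxhat - t1 - cache$xhat * t2)
  dim(dx) <- d
  list(dX = dx, dg = dg, db = db)
}

relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(dY, X) dY * (X > 0)

# 2x2 max pooling, stride 2 (floor semantics: trailing odd row/col drop).
pool_fwd <- function(X) {
  d <- dim(X)
  oh <- d[2] %/% 2L; ow <- d[3] %/% 2L
  r1 <- seq(1L, 2L * oh, 2L); r2 <- r1 + 1L
  c1 <- seq(1L, 2L * ow, 2L); c2 <- c1 + 1L
  a <- X[, r1, c1, , drop = FALSE]; b <- X[, r2, c1, , drop = FALSE]
  ce <- X[, r1, c2, , drop = FALSE]; e <- X[, r2, c2, , drop = FALSE]
  Y <- pmax(a, b, ce, e)
  m1 <- a == Y; m2 <- (b == Y) & !m1
  m3 <- (ce == Y) & !m1 & !m2; m4 <- !(m1 | m2 | m3)
  list(Y = Y, masks = list(m1, m2, m3, m4),
       rows = list(r1, r2, r1, r2), cols = list(c1, c1, c2, c2),
       in_dim = d)
}

pool_bwd <- function(dY, cache) {
  dX <- array(0, cache$in_dim)
  for (t in 1:4)
    dX[, cache$rows[[t]], cache$cols[[t]], ] <- dY * cache$masks[[t]]
  dX
}

# Nearest-neighbour upsampling to an explicit target size.
upsample_fwd <- function(X, th, tw) {
  d <- dim(X)
  ridx <- pmin(pmax(floor(((0:(th - 1)) + 0.5) * d[2] / th) + 1L, 1L), d[2])
  cidx <- pmin(pmax(floor(((0:(tw - 1)) + 0.5) * d[3] / tw) + 1L, 1L), d[3])
  list(Y = X[, ridx, cidx, , drop = FALSE], ridx = ridx, cidx = cidx,
       in_dim = d)
}

upsample_bwd <- function(dY, cache) {
  d <- cache$in_dim
  cs_upsample_bwd(dY, dim(dY), cache$ridx, cache$cidx, d[2], d[3])
}

# Numerically stable pixel-wise binary cross-entropy on logits.
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dz <- (stats::plogis(z) - y) / length(z)
  list(loss = loss, dz = dz)
}

he_init <- function(fan_out, fan_in) {
  matrix(stats::rnorm(fan_out * fan_in, 0, sqrt(2 / fan_in)), fan_out, fan_in)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
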