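## Neural-network layer primitives with hand-written gradients.
## Convolution and pooling call the C++ kernels in src/gaitnn.cpp; the dense,
## normalisation and recurrent layers below are plain R linear algebra.
## All `*_bwd` functions take the cache produced by the matching `*_fwd`.

#' Leaky rectified linear unit
#'
#' Elementwise activation: `x` for `x >= 0`, `a * x` for `x < 0`, with slope
#' `0 < a < 1`.
#'
#' @param x numeric vector, matrix or array.
#' @param a negative-side slope, strictly inside (0, 1). Default 0.01.
#' @return object of the same shape as `x`.
#' @examples
#' leaky_relu(c(-1, 0, 2), a = 0.1)
#' @export
leaky_relu <- function(x, a = 0.01) {
  if (!is.numeric(a) || length(a) != 1L || !(a > 0 && a < 1))
    stop("slope 'a' must lie strictly in (0, 1)")
  .lrelu_fwd(x, a)
}

lrelu_bwd <- function(x, dy, a) .lrelu_bwd(x, dy, a)

## dense conv wrappers around the C++ kernels ------------------------------

conv_fwd <- function(x, w, b, pad, dil = 1L) .conv2d_fwd(x, w, b, pad, dil)
conv_bwd <- function(x, w, dy, pad, dil = 1L, need_dx = TRUE)
  .conv2d_bwd(x, w, dy, pad, dil, need_dx)
## training-mode pair: forward keeps the im2col matrix for the backward pass
conv_fwd_keep <- function(x, w, b, pad, dil = 1L)
  .conv2d_fwd_keep(x, w, b, pad, dil)
conv_bwd_cached <- function(col, x, w, dy, pad, dil = 1L, need_dx = TRUE) {
  if (is.null(col)) return(.conv2d_bwd(x, w, dy, pad, dil, need_dx))
  .conv2d_bwd_cached(col, dim(x), w, dy, pad, dil, need_dx)
}
dwconv_fwd <- function(x, w, b, pad, dil = 1L) .dwconv2d_fwd(x, w, b, pad, dil)
dwconv_bwd <- function(x, w, dy, pad, dil = 1L, need_dx = TRUE)
  .dwconv2d_bwd(x, w, dy, pad, dil, need_dx)
maxpool_fwd <- function(x) .maxpool2_fwd(x)
maxpool_bwd <- function(idx, dy, xdim) .maxpool2_bwd(idx, dy, xdim)

## fully connected: W is (out x in), X is (in x B) -------------------------

fc_fwd <- function(W, b, X) W %*% X + b

fc_bwd <- function(W, X, dY) {
  list(dW = dY %*% t(X), db = rowSums(dY), dX = crossprod(W, dY))
}

## batch normalisation over rows of X (n x C); per-column statistics -------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  if (training) {
    n <- nrow(X)
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)             # biased variance, as used in the forward pass
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, invstd, `*`)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * n / max(1, n - 1)
  } else {
    invstd <- 1 / sqrt(run_var + eps)
    xhat <- sweep(sweep(X, 2L, run_mean), 2L, invstd, `*`)
  }
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(cache, dY) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, `*`)
  if (cache$training) {
    n <- nrow(xhat)
    dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat), byrow = TRUE),
                2L, cache$invstd, `*`)
  } else {
    dX <- sweep(dxhat, 2L, cache$invstd, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## LSTM over X (T x c_in x B); gate order i, f, g, o ------------------------

lstm_fwd <- function(par, X) {
  Tn <- dim(X)[1]; cin <- dim(X)[2]; B <- dim(X)[3]
  h <- nrow(par$Wh)                     # hidden size
  H <- array(0, c(Tn, h, B))
  Hprev <- matrix(0, B, h); Cprev <- matrix(0, B, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[t, , ], cin, B)        # (cin x B)
    A <- crossprod(Xt, par$Wx) + Hprev %*% par$Wh +
      matrix(par$b, B, 4 * h, byrow = TRUE)  # (B x 4h)
    i <- 1 / (1 + exp(-A[, 1:h, drop = FALSE]))
    f <- 1 / (1 + exp(-A[, h + 1:h, drop = FALSE]))
    g <- tanh(A[, 2 * h + 1:h, drop = FALSE])
    o <- 1 / (1 + exp(-A[, 3 * h + 1:h, drop = FALSE]))
    Cc <- f * Cprev + i * g
    tc <- tanh(Cc)
    Hc <- o * tc
    cache[[t]] <- list(Xt = Xt, Hprev = Hprev, Cprev = Cprev,
                       i = i, f = f, g = g, o = o, tc = tc)
    H[t, , ] <- t(Hc)
    Hprev <- Hc; Cprev <- Cc
  }
  list(H = H, cache = cache)
}

lstm_bwd <- function(par, cache, dH) {
  Tn <- dim(dH)[1]; h <- dim(dH)[2]; B <- dim(dH)[3]
  cin <- nrow(par$Wx)
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dX <- array(0, c(Tn, cin, B))
  dHnext <- matrix(0, B, h); dCnext <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dHc <- t(matrix(dH[t, , ], h, B)) + dHnext
    do <- dHc * cc$tc * cc$o * (1 - cc$o)
    dC <- dHc * cc$o * (1 - cc$tc^2) + dCnext
    di <- dC * cc$g * cc$i * (1 - cc$i)
    df <- dC * cc$Cprev * cc$f * (1 - cc$f)
    dg <- dC * cc$i * (1 - cc$g^2)
    dA <- cbind(di, df, dg, do)           # (B x 4h)
    dWx <- dWx + cc$Xt %*% dA
    dWh <- dWh + crossprod(cc$Hprev, dA)
    db <- db + colSums(dA)
    dX[t, , ] <- tcrossprod(par$Wx, dA)   # (cin x B)
    dHnext <- tcrossprod(dA, par$Wh)      # dA %*% t(Wh): (B x h)
    dCnext <- dC * cc$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## bidirectional LSTM: forward stream + time-reversed stream, channel concat
bilstm_fwd <- function(par, X) {
  Tn <- dim(X)[1]
  fwd <- lstm_fwd(par$fwd, X)
  Xr <- X[rev(seq_len(Tn)), , , drop = FALSE]
  bwd <- lstm_fwd(par$bwd, Xr)
  Hb <- bwd$H[rev(seq_len(Tn)), , , drop = FALSE]
  H <- array(0, c(Tn, dim(fwd$H)[2] + dim(Hb)[2], dim(X)[3]))
  H[, seq_len(dim(fwd$H)[2]), ] <- fwd$H
  H[, dim(fwd$H)[2] + seq_len(dim(Hb)[2]), ] <- Hb
  list(H = H, cache = list(fwd = fwd$cache, bwd = bwd$cache,
                           h = dim(fwd$H)[2]))
}

bilstm_bwd <- function(par, cache, dH) {
  Tn <- dim(dH)[1]; h <- cache$h
  dHf <- dH[, seq_len(h), , drop = FALSE]
  dHb <- dH[, h + seq_len(dim(dH)[2] - h), , drop = FALSE]
  gf <- lstm_bwd(par$fwd, cache$fwd, dHf)
  gb <- lstm_bwd(par$bwd, cache$bwd, dHb[rev(seq_len(Tn)), , , drop = FALSE])
  dX <- gf$dX + gb$dX[rev(seq_len(Tn)), , , drop = FALSE]
  list(dX = dX, fwd = gf[c("dWx", "dWh", "db")], bwd = gb[c("dWx", "dWh", "db")])
}

## inverted dropout --------------------------------------------------------

dropout_fwd <- function(x, rate, training, seed = NULL) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- if (is.null(seed)) (runif(length(x)) >= rate) / (1 - rate)
  else with_seed(seed, (runif(length(x)) >= rate) / (1 - rate))
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(mask, dy) if (is.null(mask)) dy else dy * mask

## initialisers ------------------------------------------------------------

init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(W = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_dwconv <- function(k, c) {
  sd <- sqrt(2 / (k * k))
  list(W = array(rnorm(k * k * c, 0, sd), c(k, k, c)), b = numeric(c))
}

init_fc <- function(din, dout) {
  sd <- sqrt(1 / din)
  list(W = matrix(rnorm(dout * din, 0, sd), dout, din), b = numeric(dout))
}

init_lstm <- function(cin, h) {
  s <- 1 / sqrt(h)
  b <- runif(4 * h, -s, s)
  b[h + 1:h] <- b[h + 1:h] + 1        # forget-gate bias offset
  list(Wx = matrix(runif(cin * 4 * h, -s, s), cin, 4 * h),
       Wh = matrix(runif(h * 4 * h, -s, s), h, 4 * h),
       b = b)
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

## Adam --------------------------------------------------------------------

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(st$m, grad, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- tree_map2(st$v, grad, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  upd <- tree_map2(st$m, st$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  par <- tree_map2(par, upd, `-`)
  list(par = par, st = st)
}

adam_init <- function(par) list(m = tree_zeros(par), v = tree_zeros(par), t = 0L)
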