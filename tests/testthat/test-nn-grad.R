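## Finite-difference verification of the hand-written layer gradients.
## Convolution kernels run in single precision, so their checks use a looser
## relative tolerance; the R-side layers are double precision.

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

relerr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

test_that("dense and dilated convolution gradients match finite differences", {
  ns <- asNamespace("gaitscreen")
  set.seed(42)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3, 3, 2, 3))
  b <- rnorm(3)
  for (cfgc in list(c(pad = 1L, dil = 1L), c(pad = 2L, dil = 2L))) {
    y0 <- ns$conv_fwd(x, w, b, cfgc["pad"], cfgc["dil"])
    dy <- array(rnorm(length(y0)), dim(y0))
    g <- ns$conv_bwd(x, w, dy, cfgc["pad"], cfgc["dil"], TRUE)
    loss_x <- function(v) sum(ns$conv_fwd(array(v, dim(x)), w, b,
                                          cfgc["pad"], cfgc["dil"]) * dy)
    loss_w <- function(v) sum(ns$conv_fwd(x, array(v, dim(w)), b,
                                          cfgc["pad"], cfgc["dil"]) * dy)
    expect_lt(relerr(g$dx, array(fd_grad(loss_x, as.vector(x), 1e-3), dim(x))), 2e-3)
    expect_lt(relerr(g$dw, array(fd_grad(loss_w, as.vector(w), 1e-3), dim(w))), 2e-3)
  }
  ## the col-caching training path agrees exactly with the recompute path
  fk <- ns$conv_fwd_keep(x, w, b, 1L, 1L)
  dy <- array(rnorm(length(fk$y)), dim(fk$y))
  g1 <- ns$conv_bwd_cached(fk$col, x, w, dy, 1L, 1L, TRUE)
  g2 <- ns$conv_bwd(x, w, dy, 1L, 1L, TRUE)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(fk$y, ns$conv_fwd(x, w, b, 1L, 1L), tolerance = 1e-12)
})

test_that("depth-wise convolution and max-pooling gradients are exact", {
  ns <- asNamespace("gaitscreen")
  set.seed(43)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  w <- array(rnorm(3 * 3 * 3), c(3, 3, 3)); b <- rnorm(3)
  y0 <- ns$dwconv_fwd(x, w, b, 2L, 2L)
  dy <- array(rnorm(length(y0)), dim(y0))
  g <- ns$dwconv_bwd(x, w, dy, 2L, 2L, TRUE)
  lx <- function(v) sum(ns$dwconv_fwd(array(v, dim(x)), w, b, 2L, 2L) * dy)
  lw <- function(v) sum(ns$dwconv_fwd(x, array(v, dim(w)), b, 2L, 2L) * dy)
  expect_lt(relerr(g$dx, array(fd_grad(lx, as.vector(x)), dim(x))), 1e-8)
  expect_lt(relerr(g$dw, array(fd_grad(lw, as.vector(w)), dim(w))), 1e-8)
  mp <- ns$maxpool_fwd(x)
  dyp <- array(rnorm(length(mp$y)), dim(mp$y))
  gm <- ns$maxpool_bwd(mp$idx, dyp, dim(x))
  fdm <- fd_grad(function(v) sum(ns$maxpool_fwd(array(v, dim(x)))$y * dyp),
                 as.vector(x), 1e-4)
  expect_lt(relerr(gm, array(fdm, dim(x))), 1e-8)
})

test_that("batch-norm and LSTM gradients match finite differences", {
  ns <- asNamespace("gaitscreen")
  set.seed(44)
  X <- matrix(rnorm(40), 8, 5)
  gam <- runif(5, 0.5, 1.5); bet <- rnorm(5)
  dY <- matrix(rnorm(40), 8, 5)
  f <- function(xx, gg, bb) sum(ns$bn_fwd(matrix(xx, 8, 5), gg, bb, numeric(5),
                                          rep(1, 5), TRUE)$y * dY)
  bn <- ns$bn_fwd(X, gam, bet, numeric(5), rep(1, 5), TRUE)
  gb <- ns$bn_bwd(bn$cache, dY)
  expect_lt(relerr(gb$dX, matrix(fd_grad(function(v) f(v, gam, bet),
                                         as.vector(X)), 8, 5)), 1e-6)
  expect_lt(relerr(gb$dgamma, fd_grad(function(v) f(X, v, bet), gam)), 1e-6)
  par <- ns$with_seed(7, ns$init_lstm(3, 2))
  X3 <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  dH <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  gl <- ns$lstm_bwd(par, ns$lstm_fwd(par, X3)$cache, dH)
  fl <- function(xx) sum(ns$lstm_fwd(par, array(xx, dim(X3)))$H * dH)
  expect_lt(relerr(gl$dX, array(fd_grad(fl, as.vector(X3)), dim(X3))), 1e-6)
  fwx <- function(v) { p2 <- par; p2$Wx[] <- v; sum(ns$lstm_fwd(p2, X3)$H * dH) }
  expect_lt(relerr(gl$dWx, matrix(fd_grad(fwx, as.vector(par$Wx)), 3, 8)), 1e-6)
})

test_that("the assembled MTM gradient matches finite differences", {
  ns <- asNamespace("gaitscreen")
  spec <- mtm_spec(c1 = 4, attention_reduction = 2, dropout_rate = 0)
  pm <- ns$mtm_init(spec, 3)
  st <- ns$mtm_state_init(spec)
  set.seed(45)
  Xm <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  dout <- matrix(rnorm(spec$c2 * 3), spec$c2, 3)
  mf <- ns$mtm_fwd_cached(pm, Xm, spec, st, TRUE)
  mb <- ns$mtm_bwd(pm, mf$cache, spec, dout)
  fm <- function(xx) sum(ns$mtm_fwd_cached(pm, array(xx, dim(Xm)), spec, st,
                                           TRUE)$out * dout)
  expect_lt(relerr(mb$dX, array(fd_grad(fm, as.vector(Xm)), dim(Xm))), 1e-6)
  for (pth in list(c("bn1", "gamma"), c("bn2", "beta"), c("att1", "W"))) {
    leaf <- pm[[pth[1]]][[pth[2]]]
    fp <- function(v) {
      p2 <- pm; p2[[pth[1]]][[pth[2]]][] <- v
      sum(ns$mtm_fwd_cached(p2, Xm, spec, st, TRUE)$out * dout)
    }
    expect_lt(relerr(as.vector(mb$grads[[pth[1]]][[pth[2]]]),
                     fd_grad(fp, as.vector(leaf))), 1e-6)
  }
})

test_that("triplet and cross-entropy gradients match finite differences", {
  ns <- asNamespace("gaitscreen")
  set.seed(46)
  emb <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  labs <- c(1, 1, 2, 2, 3, 3)
  tr <- ba_triplet_loss(emb, labs, 0.3, gradient = TRUE)
  fdt <- fd_grad(function(v) ba_triplet_loss(array(v, dim(emb)), labs,
                                             0.3)$loss, as.vector(emb), 1e-6)
  expect_lt(relerr(tr$grad, array(fdt, dim(emb))), 1e-5)
  lg <- matrix(rnorm(12), 4, 3); yy <- c(1, 2, 3, 1)
  ce <- label_smoothing_ce(lg, yy, 0.1, gradient = TRUE)
  fdc <- fd_grad(function(v) label_smoothing_ce(matrix(v, 4, 3), yy, 0.1),
                 as.vector(lg), 1e-6)
  expect_lt(relerr(ce$grad, matrix(fdc, 4, 3)), 1e-6)
})
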