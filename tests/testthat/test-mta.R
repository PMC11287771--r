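test_that("mtm_spec enforces its width invariants", {
  expect_error(mtm_spec(c1 = 8, bilstm_hidden = 3), "c1 / 2")
  expect_error(mtm_spec(c1 = 8, attention_reduction = 5), "divide")
  expect_error(mtm_spec(c1 = 8, dropout_rate = 1), "dropout")
  expect_error(mtm_spec(c1 = 8, use_frame_branch = FALSE, recurrent = "none"),
               "branch")
  s <- mtm_spec(c1 = 8, attention_reduction = 4)
  expect_identical(s$c2, 16L)
  expect_identical(s$bilstm_hidden, 4L)
  ## reference widths: c1 = 192 with r = 16 gives a bottleneck of 24
  s192 <- mtm_spec(c1 = 192)
  p192 <- gaitscreen:::mtm_init(s192, 1)
  expect_identical(nrow(p192$att1$W), 384L %/% 16L)
  expect_identical(ncol(p192$att1$W), 384L)
})

test_that("a vanishing recurrent path makes f_ls equal f_f (residual identity)", {
  spec <- mtm_spec(c1 = 6, attention_reduction = 4, dropout_rate = 0,
                   use_attention = FALSE)
  par <- gaitscreen:::mtm_init(spec, 2)
  ## zero the BiLSTM output path (output weights and biases)
  for (d in c("fwd", "bwd")) {
    par$lstm[[d]]$Wx[] <- 0; par$lstm[[d]]$Wh[] <- 0; par$lstm[[d]]$b[] <- 0
  }
  ## with zeroed gates the cell output is o*tanh(c) = 0.5*tanh(0) = 0
  X <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  st <- gaitscreen:::mtm_state_init(spec)
  r <- gaitscreen:::bilstm_fwd(par$lstm, X)
  expect_true(all(abs(r$H) < 1e-12))
  ## in eval mode both BatchNorms are near-identity (zero mean, unit variance
  ## running statistics), so f_ls = f_f up to the epsilon regulariser
  out <- gaitscreen:::mtm_fwd_cached(par, X, spec, st, training = FALSE)
  Ff_pool <- apply(X, c(2, 3), max)
  expect_equal(out$out[seq_len(6), ], Ff_pool, tolerance = 1e-4)
  expect_equal(out$out[6 + seq_len(6), ], Ff_pool, tolerance = 1e-4)
})

test_that("a single-frame sequence is handled (temporal max of one step)", {
  spec <- mtm_spec(c1 = 4, attention_reduction = 2, dropout_rate = 0)
  v <- mtm_forward(matrix(rnorm(4), 1, 4), spec, seed = 6)
  expect_length(v, spec$c2)
  expect_true(all(is.finite(v)))
})

test_that("frame order affects the recurrent branch but not the frame branch", {
  ## without channel attention the pooled frame-branch channels are a
  ## temporal max of per-frame features, hence order-invariant; the
  ## recurrent branch is order-sensitive
  spec <- mtm_spec(c1 = 6, use_attention = FALSE, dropout_rate = 0)
  par <- gaitscreen:::mtm_init(spec, 3)
  st <- gaitscreen:::mtm_state_init(spec)
  X <- array(rnorm(5 * 6 * 2), c(5, 6, 2))
  Xr <- X[5:1, , , drop = FALSE]
  o1 <- gaitscreen:::mtm_fwd_cached(par, X, spec, st, training = FALSE)$out
  o2 <- gaitscreen:::mtm_fwd_cached(par, Xr, spec, st, training = FALSE)$out
  expect_equal(o1[seq_len(6), ], o2[seq_len(6), ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(o1[6 + seq_len(6), ], o2[6 + seq_len(6), ])))
})

test_that("BiLSTM direction symmetry holds exactly", {
  ## swapping the forward/backward parameter sets and reversing time yields
  ## the time-reversed, direction-swapped output (T = 5, c1 = 8)
  par <- gaitscreen:::with_seed(11, list(fwd = gaitscreen:::init_lstm(8, 4),
                                         bwd = gaitscreen:::init_lstm(8, 4)))
  sw <- list(fwd = par$bwd, bwd = par$fwd)
  X <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
  Xr <- X[5:1, , , drop = FALSE]
  H1 <- gaitscreen:::bilstm_fwd(par, X)$H
  H2 <- gaitscreen:::bilstm_fwd(sw, Xr)$H
  expect_equal(H2[5:1, 5:8, , drop = FALSE], H1[, 1:4, , drop = FALSE],
               tolerance = 1e-14)
  expect_equal(H2[5:1, 1:4, , drop = FALSE], H1[, 5:8, , drop = FALSE],
               tolerance = 1e-14)
})

test_that("the attention stack gates channels and is inert in eval mode", {
  spec <- mtm_spec(c1 = 4, attention_reduction = 2, dropout_rate = 0.5)
  par <- gaitscreen:::mtm_init(spec, 5)
  z <- matrix(rnorm(8 * 6), 8, 6)
  ## eval mode: dropout inert, repeated calls identical
  a1 <- attention_stack(z, spec, par, training = FALSE)
  a2 <- attention_stack(z, spec, par, training = FALSE)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(z))
  ## gate forced to all-ones reproduces the input: zero the first conv so the
  ## bottleneck is constant, then bias the second conv to exactly 1
  par1 <- par
  par1$att1$W[] <- 0; par1$att1$b[] <- 0
  par1$att2$W[] <- 0; par1$att2$b[] <- 1
  expect_equal(attention_stack(z, spec, par1, training = FALSE), z,
               tolerance = 1e-12)
})

test_that("MTMs act on parts independently and in parallel", {
  spec <- mtm_spec(c1 = 4, attention_reduction = 2, dropout_rate = 0)
  set.seed(21)
  FHP <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  params <- lapply(1:3, function(j) gaitscreen:::mtm_init(spec, 30 + j))
  out <- mta_forward(FHP, spec, params)
  expect_identical(dim(out$F_MTA), c(8L, 3L))
  expect_identical(dim(out$F_f), c(4L, 3L))
  ## permuting parts (with their parameters) permutes output columns
  perm <- c(3, 1, 2)
  out_p <- mta_forward(FHP[, , perm], spec, params[perm])
  expect_equal(out_p$F_MTA, out$F_MTA[, perm], tolerance = 1e-12)
  ## zeroing part j's input changes only column j
  FHP0 <- FHP; FHP0[, , 2] <- 0
  out0 <- mta_forward(FHP0, spec, params)
  expect_equal(out0$F_MTA[, c(1, 3)], out$F_MTA[, c(1, 3)], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out0$F_MTA[, 2], out$F_MTA[, 2])))
  ## p = 1 reduces to a single MTM
  one <- mta_forward(FHP[, , 1, drop = FALSE], spec, params[1])
  expect_equal(one$F_MTA[, 1],
               mtm_forward(matrix(FHP[, , 1], 6, 4), spec, params[[1]]),
               tolerance = 1e-12)
})

test_that("the embedding head is a per-part FC + BN with BNNeck outputs", {
  set.seed(31)
  FMTA <- matrix(rnorm(8 * 3), 8, 3)
  params <- lapply(1:3, function(j) gaitscreen:::head_init(8, 5, 2, 40 + j))
  E <- head_forward(FMTA, d = 5, params = params)
  expect_identical(dim(E), c(3L, 5L))
  expect_identical(dim(attr(E, "pre_bn")), c(3L, 5L))
  ## per-part independence
  F2 <- FMTA; F2[, 2] <- F2[, 2] + 1
  E2 <- head_forward(F2, d = 5, params = params)
  expect_equal(E2[c(1, 3), ], E[c(1, 3), ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(E2[2, ], E[2, ])))
  ## eval-mode BN with loaded statistics is an affine map
  st <- list(bn = list(mean = rnorm(5), var = runif(5, 0.5, 2)))
  hf <- gaitscreen:::head_fwd_cached(params[[1]], FMTA[, 1, drop = FALSE],
                                     st, training = FALSE)
  pre <- as.vector(hf$e_pre)
  gam <- params[[1]]$bn$gamma; bet <- params[[1]]$bn$beta
  affine <- gam * (pre - st$bn$mean) / sqrt(st$bn$var + 1e-5) + bet
  expect_equal(as.vector(hf$e_post), affine, tolerance = 1e-12)
})

test_that("all MTM variants produce well-formed features", {
  ## frame-only, LSTM, BiLSTM, each with and without channel attention
  X <- matrix(rnorm(6 * 8), 6, 8)
  grid <- expand.grid(recurrent = c("none", "lstm", "bilstm"),
                      att = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    rec <- grid$recurrent[i]
    spec <- mtm_spec(c1 = 8, attention_reduction = 4, dropout_rate = 0,
                     use_frame_branch = rec == "none" || rec == "bilstm",
                     recurrent = rec, use_attention = grid$att[i])
    v <- mtm_forward(X, spec, seed = 50 + i)
    expect_length(v, spec$c2)
    expect_true(all(is.finite(v)))
  }
  ## mean temporal pooling (diagnostics) also well-formed
  spm <- mtm_spec(c1 = 8, attention_reduction = 4, dropout_rate = 0,
                  tp_mode = "mean")
  vm <- mtm_forward(X, spm, seed = 3)
  expect_length(vm, spm$c2)
})
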