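## Multi-scale temporal aggregation: one multi-scale temporal module (MTM)
## per horizontal part, with independent parameters. Per part j the frame
## sequence f_HP^j (T x c1) is processed as
##
##   f_f  = BatchNorm(f_HP)                          frame-level branch
##   f_ls = BatchNorm(f_f + BiLSTM(f_HP))            long short-term branch
##   f_MTA = TP( Attention( Concat(f_f, f_ls) ) )    TP = temporal max
##
## where the BiLSTM concatenates both directions to width c1 (hidden size
## c1/2 per direction, so the residual sum is well defined) and Attention is
## a squeeze-excitation-style channel gate computed from the temporal mean
## descriptor: Conv1d (1x1, reduction r) -> LeakyReLU -> Dropout -> Conv1d
## (1x1) -> LeakyReLU, multiplied into the channels. The embedding head then
## maps each part feature through an independent fully connected layer and
## batch normalisation; the triplet loss reads the pre-BN features and the
## classifier the post-BN features (BNNeck arrangement).

#' Multi-scale temporal module specification
#'
#' @param c1 channels per part entering the module.
#' @param bilstm_hidden hidden width per direction; defaults to `c1 / 2` so
#'   the bidirectional output matches `c1` for the residual sum.
#' @param attention_reduction squeeze ratio r of the channel-attention
#'   bottleneck; must divide the concatenated channel count.
#' @param dropout_rate dropout probability inside the attention stack, \[0, 1).
#' @param leaky_slope LeakyReLU slope, (0, 1).
#' @param use_frame_branch include the frame-level branch.
#' @param recurrent `"bilstm"`, `"lstm"` or `"none"` (ablation variants).
#' @param use_attention apply the channel-attention gate.
#' @param attention_sigmoid append a sigmoid to bound the gates in (0, 1);
#'   the default keeps the literal two-convolution + LeakyReLU stack.
#' @param tp_mode temporal pooling, `"max"` (default) or `"mean"`
#'   (diagnostics only).
#' @return object of class `"mtm_spec"`.
#' @export
mtm_spec <- function(c1, bilstm_hidden = NULL, attention_reduction = 16L,
                     dropout_rate = 0.2, leaky_slope = 0.01,
                     use_frame_branch = TRUE,
                     recurrent = c("bilstm", "lstm", "none"),
                     use_attention = TRUE, attention_sigmoid = FALSE,
                     tp_mode = c("max", "mean")) {
  recurrent <- match.arg(recurrent)
  tp_mode <- match.arg(tp_mode)
  c1 <- as.integer(c1)
  h <- as.integer(bilstm_hidden %||% (c1 %/% 2L))
  if (recurrent == "bilstm" && 2L * h != c1)
    stop("bilstm_hidden must equal c1 / 2 (residual-sum compatibility)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  if (!use_frame_branch && recurrent == "none")
    stop("at least one of the frame-level and recurrent branches is required")
  cz <- c1 * (as.integer(use_frame_branch) + as.integer(recurrent != "none"))
  if (use_attention && cz %% attention_reduction != 0)
    stop(sprintf("attention_reduction %d does not divide channel width %d",
                 attention_reduction, cz))
  structure(list(c1 = c1, bilstm_hidden = h,
                 attention_reduction = as.integer(attention_reduction),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 use_frame_branch = use_frame_branch, recurrent = recurrent,
                 use_attention = use_attention,
                 attention_sigmoid = attention_sigmoid,
                 tp_mode = tp_mode, c2 = cz),
            class = "mtm_spec")
}

mtm_init <- function(spec, seed = 1L) {
  with_seed(seed, {
    p <- list(bn1 = init_bn(spec$c1))
    if (spec$recurrent == "bilstm") {
      p$lstm <- list(fwd = init_lstm(spec$c1, spec$bilstm_hidden),
                     bwd = init_lstm(spec$c1, spec$bilstm_hidden))
      p$bn2 <- init_bn(spec$c1)
    } else if (spec$recurrent == "lstm") {
      p$lstm <- init_lstm(spec$c1, spec$c1)
      p$bn2 <- init_bn(spec$c1)
    }
    if (spec$use_attention) {
      p$att1 <- init_fc(spec$c2, spec$c2 %/% spec$attention_reduction)
      p$att2 <- init_fc(spec$c2 %/% spec$attention_reduction, spec$c2)
    }
    p
  })
}

mtm_state_init <- function(spec) {
  st <- list(bn1 = list(mean = numeric(spec$c1), var = rep(1, spec$c1)))
  if (spec$recurrent != "none")
    st$bn2 <- list(mean = numeric(spec$c1), var = rep(1, spec$c1))
  st
}

## attention gate from a (cz x B) descriptor; returns gate and cache
attention_gate <- function(par, s, spec, training, seed = NULL) {
  a1 <- fc_fwd(par$att1$W, par$att1$b, s)
  h1 <- leaky_relu(a1, spec$leaky_slope)
  dp <- dropout_fwd(h1, spec$dropout_rate, training, seed)
  a2 <- fc_fwd(par$att2$W, par$att2$b, dp$y)
  g <- leaky_relu(a2, spec$leaky_slope)
  if (spec$attention_sigmoid) g <- 1 / (1 + exp(-g))
  list(g = g, cache = list(s = s, a1 = a1, h1 = h1, mask = dp$mask,
                           h1d = dp$y, a2 = a2, g = g))
}

attention_gate_bwd <- function(par, cache, spec, dg) {
  if (spec$attention_sigmoid) dg <- dg * cache$g * (1 - cache$g)
  dg <- lrelu_bwd(cache$a2, dg, spec$leaky_slope)
  g2 <- fc_bwd(par$att2$W, cache$h1d, dg)
  dh1 <- dropout_bwd(cache$mask, g2$dX)
  dh1 <- lrelu_bwd(cache$a1, dh1, spec$leaky_slope)
  g1 <- fc_bwd(par$att1$W, cache$s, dh1)
  list(ds = g1$dX,
       att1 = list(W = g1$dW, b = g1$db), att2 = list(W = g2$dW, b = g2$db))
}

## cached forward for one part; X is (T x c1 x B)
mtm_fwd_cached <- function(par, X, spec, state, training, seed = NULL,
                           momentum = 0.1) {
  Tn <- dim(X)[1]; c1 <- dim(X)[2]; B <- dim(X)[3]
  if (Tn < 1) stop("empty frame sequence")
  Xm <- matrix(aperm(X, c(1, 3, 2)), Tn * B, c1)
  b1 <- bn_fwd(Xm, par$bn1$gamma, par$bn1$beta, state$bn1$mean, state$bn1$var,
               training, momentum)
  state$bn1$mean <- b1$run_mean; state$bn1$var <- b1$run_var
  Ff <- aperm(array(b1$y, c(Tn, B, c1)), c(1, 3, 2))
  branches <- list(); cache <- list(b1 = b1$cache, dims = dim(X))
  if (spec$recurrent != "none") {
    if (spec$recurrent == "bilstm") {
      r <- bilstm_fwd(par$lstm, X)
    } else {
      r <- lstm_fwd(par$lstm, X)
    }
    pre <- Ff + r$H
    prem <- matrix(aperm(pre, c(1, 3, 2)), Tn * B, c1)
    b2 <- bn_fwd(prem, par$bn2$gamma, par$bn2$beta, state$bn2$mean,
                 state$bn2$var, training, momentum)
    state$bn2$mean <- b2$run_mean; state$bn2$var <- b2$run_var
    Fls <- aperm(array(b2$y, c(Tn, B, c1)), c(1, 3, 2))
    cache$lstm <- r$cache; cache$b2 <- b2$cache
    if (spec$use_frame_branch) branches <- list(Ff, Fls) else branches <- list(Fls)
  } else {
    branches <- list(Ff)
  }
  cz <- spec$c2
  z <- array(0, c(Tn, cz, B))
  for (i in seq_along(branches))
    z[, (i - 1) * c1 + seq_len(c1), ] <- branches[[i]]
  if (spec$use_attention) {
    s <- matrix(apply(z, c(2, 3), mean), cz, B)
    ag <- attention_gate(par, s, spec, training, seed)
    ## broadcast gates g (cz x B) over the time axis
    zw <- z * array(rep(as.vector(ag$g), each = Tn), c(Tn, cz, B))
    cache$att <- ag$cache
  } else {
    zw <- z
  }
  cache$z <- z
  if (spec$tp_mode == "max") {
    ## temporal max over T per (channel, sequence)
    zz <- matrix(zw, Tn, cz * B)
    am <- max.col(t(zz), ties.method = "first")
    out <- matrix(zz[cbind(am, seq_len(cz * B))], cz, B)
    cache$tp_amax <- am
  } else {
    out <- matrix(colMeans(matrix(zw, Tn, cz * B)), cz, B)
  }
  cache$Tn <- Tn
  list(out = out, cache = cache, state = state)
}

mtm_bwd <- function(par, cache, spec, dout) {
  Tn <- cache$Tn
  d <- cache$dims; c1 <- d[2]; B <- d[3]; cz <- spec$c2
  ## through temporal pooling
  dzw <- array(0, c(Tn, cz, B))
  if (!is.null(cache$tp_amax)) {
    dzz <- matrix(0, Tn, cz * B)
    dzz[cbind(cache$tp_amax, seq_len(cz * B))] <- as.vector(dout)
    dzw[] <- dzz
  } else {
    dzw[] <- rep(as.vector(dout) / Tn, each = Tn)
  }
  grads <- list()
  if (spec$use_attention) {
    Gb <- array(rep(as.vector(cache$att$g), each = Tn), c(Tn, cz, B))
    dz <- dzw * Gb
    dG <- matrix(apply(dzw * cache$z, c(2, 3), sum), cz, B)
    ab <- attention_gate_bwd(par, cache$att, spec, dG)
    grads$att1 <- ab$att1; grads$att2 <- ab$att2
    dz <- dz + array(rep(as.vector(ab$ds / Tn), each = Tn), c(Tn, cz, B))
  } else {
    dz <- dzw
  }
  dim(dz) <- c(Tn, cz, B)
  ## split concatenated channels back into branches
  nb <- cz %/% c1
  dbr <- lapply(seq_len(nb), function(i) dz[, (i - 1) * c1 + seq_len(c1), , drop = FALSE])
  dX <- array(0, d)
  dFf <- array(0, d)
  bi <- 0L
  if (spec$use_frame_branch) { bi <- 1L; dFf <- dFf + array(dbr[[1]], d) }
  if (spec$recurrent != "none") {
    dFls <- array(dbr[[bi + 1L]], d)
    dflsm <- matrix(aperm(dFls, c(1, 3, 2)), Tn * B, c1)
    b2 <- bn_bwd(cache$b2, dflsm)
    grads$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
    dpre <- aperm(array(b2$dX, c(Tn, B, c1)), c(1, 3, 2))
    dFf <- dFf + dpre
    if (spec$recurrent == "bilstm") {
      lb <- bilstm_bwd(par$lstm, cache$lstm, dpre)
      grads$lstm <- list(fwd = list(Wx = lb$fwd$dWx, Wh = lb$fwd$dWh, b = lb$fwd$db),
                         bwd = list(Wx = lb$bwd$dWx, Wh = lb$bwd$dWh, b = lb$bwd$db))
    } else {
      lb <- lstm_bwd(par$lstm, cache$lstm, dpre)
      grads$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
    }
    dX <- dX + lb$dX
  }
  dffm <- matrix(aperm(dFf, c(1, 3, 2)), Tn * B, c1)
  b1 <- bn_bwd(cache$b1, dffm)
  grads$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  dX <- dX + aperm(array(b1$dX, c(Tn, B, c1)), c(1, 3, 2))
  ## order grads like the parameter list
  out <- list(bn1 = grads$bn1)
  if (spec$recurrent != "none") { out$lstm <- grads$lstm; out$bn2 <- grads$bn2 }
  if (spec$use_attention) { out$att1 <- grads$att1; out$att2 <- grads$att2 }
  list(grads = out, dX = dX)
}

#' Multi-scale temporal module forward pass
#'
#' Aggregates one part's frame-feature sequence (T x c1) into a fixed-length
#' feature vector via the frame-level and recurrent branches, channel
#' attention and temporal pooling.
#'
#' @param f_hp_j matrix T x c1: the part's per-frame descriptors.
#' @param spec an [mtm_spec()].
#' @param params parameter list from [mta_forward()]-style initialisation;
#'   drawn with `seed` when `NULL`.
#' @param training logical; training mode uses batch statistics and active
#'   dropout, evaluation mode running statistics and inert dropout.
#' @param seed seed for initialisation / dropout.
#' @return numeric vector of length `spec$c2`.
#' @export
mtm_forward <- function(f_hp_j, spec, params = NULL, training = FALSE, seed = 1L) {
  if (!is.matrix(f_hp_j)) stop("f_hp_j must be a T x c1 matrix")
  params <- params %||% mtm_init(spec, seed)
  X <- array(f_hp_j, c(nrow(f_hp_j), ncol(f_hp_j), 1L))
  drop(mtm_fwd_cached(params, X, spec, mtm_state_init(spec), training,
                      seed = derive_seed(seed, "mtm-dropout"))$out)
}

#' Channel-attention stack
#'
#' Squeeze-excitation-style gate: the temporal mean descriptor is passed
#' through a 1x1 bottleneck convolution pair with LeakyReLU and dropout, and
#' the resulting per-channel gates scale the input features.
#'
#' @param z matrix channels x T.
#' @param spec an [mtm_spec()] whose `c2` matches `nrow(z)`.
#' @param params parameter list; drawn with `seed` when `NULL`.
#' @param training dropout active if `TRUE`.
#' @param seed initialisation / dropout seed.
#' @return matrix of the same shape as `z`, channel-weighted.
#' @export
attention_stack <- function(z, spec, params = NULL, training = FALSE, seed = 1L) {
  if (!spec$use_attention) return(z)
  params <- params %||% mtm_init(spec, seed)
  s <- matrix(rowMeans(z), ncol = 1)
  g <- attention_gate(params, s, spec, training,
                      seed = derive_seed(seed, "att-dropout"))$g
  z * as.vector(g)
}

#' Multi-scale temporal aggregation over all parts
#'
#' Applies one independently parameterised MTM per part (no cross-part
#' mixing).
#'
#' @param F_HP array `(T, c1, p)`: the part feature tensor.
#' @param spec an [mtm_spec()].
#' @param params list of `p` MTM parameter lists; drawn with `seed` when `NULL`.
#' @param training training/eval mode.
#' @param seed initialisation / dropout seed.
#' @return list of class `"multi_scale_feature"` with `F_MTA` (c2 x p) and,
#'   when both branches are active, the temporally pooled branch features
#'   `F_f` and `F_ls` (c1 x p each).
#' @export
mta_forward <- function(F_HP, spec, params = NULL, training = FALSE, seed = 1L) {
  if (length(dim(F_HP)) != 3) stop("F_HP must be a (T, c1, p) array")
  p <- dim(F_HP)[3]
  if (p < 1) stop("p must be >= 1")
  params <- params %||% lapply(seq_len(p), function(j)
    mtm_init(spec, derive_seed(seed, "mtm", j)))
  cols <- lapply(seq_len(p), function(j)
    mtm_forward(matrix(F_HP[, , j], dim(F_HP)[1], dim(F_HP)[2]), spec,
                params[[j]], training, seed = derive_seed(seed, "fwd", j)))
  F_MTA <- do.call(cbind, cols)
  out <- list(F_MTA = F_MTA)
  if (spec$use_frame_branch && spec$recurrent != "none") {
    c1 <- spec$c1
    out$F_f <- F_MTA[seq_len(c1), , drop = FALSE]
    out$F_ls <- F_MTA[c1 + seq_len(c1), , drop = FALSE]
  }
  structure(out, class = "multi_scale_feature")
}

## ---- embedding head ------------------------------------------------------

head_init <- function(c_in, d, n_class, seed = 1L) {
  with_seed(seed, list(fc = init_fc(c_in, d), bn = init_bn(d),
                       cls = init_fc(d, n_class)))
}

head_state_init <- function(d) list(bn = list(mean = numeric(d), var = rep(1, d)))

## f (c_in x B) -> pre-BN embedding, post-BN embedding, logits
head_fwd_cached <- function(par, f, state, training, momentum = 0.1) {
  e_pre <- fc_fwd(par$fc$W, par$fc$b, f)            # d x B
  bn <- bn_fwd(t(e_pre), par$bn$gamma, par$bn$beta, state$bn$mean,
               state$bn$var, training, momentum)
  state$bn$mean <- bn$run_mean; state$bn$var <- bn$run_var
  e_post <- t(bn$y)                                  # d x B
  logits <- fc_fwd(par$cls$W, par$cls$b, e_post)     # C x B
  list(e_pre = e_pre, e_post = e_post, logits = logits,
       cache = list(f = f, e_pre = e_pre, bn = bn$cache, e_post = e_post),
       state = state)
}

head_bwd <- function(par, cache, dlogits, de_pre_extra) {
  gc <- fc_bwd(par$cls$W, cache$e_post, dlogits)
  bb <- bn_bwd(cache$bn, t(gc$dX))
  de_pre <- t(bb$dX) + de_pre_extra
  gf <- fc_bwd(par$fc$W, cache$f, de_pre)
  list(grads = list(fc = list(W = gf$dW, b = gf$db),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta),
                    cls = list(W = gc$dW, b = gc$db)),
       df = gf$dX)
}

#' Per-part embedding head
#'
#' Maps each part's aggregated feature through an independent fully
#' connected layer and batch normalisation. The returned matrix holds the
#' post-BN embeddings (classifier input); the pre-BN features used by the
#' triplet loss are available as attribute `"pre_bn"`.
#'
#' @param F_MTA matrix `c2 x p` (one column per part).
#' @param d embedding width per part.
#' @param params list of `p` head parameter lists; drawn with `seed` if `NULL`.
#' @param training training/eval mode for the batch normalisation.
#' @param seed initialisation seed.
#' @return `p x d` embedding matrix with attribute `"pre_bn"`.
#' @export
head_forward <- function(F_MTA, d = 128L, params = NULL, training = FALSE,
                         seed = 1L) {
  p <- ncol(F_MTA)
  params <- params %||% lapply(seq_len(p), function(j)
    head_init(nrow(F_MTA), d, 2L, derive_seed(seed, "head", j)))
  pre <- matrix(0, p, d); post <- matrix(0, p, d)
  for (j in seq_len(p)) {
    hf <- head_fwd_cached(params[[j]], F_MTA[, j, drop = FALSE],
                          head_state_init(d), training)
    pre[j, ] <- hf$e_pre; post[j, ] <- hf$e_post
  }
  structure(post, pre_bn = pre)
}
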