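## Training internals: P x K batch construction, the per-iteration
## forward/backward pass, embedding extraction and checkpointing.

## one epoch's batches: subjects shuffled, grouped into ceiling(S/P) batches
## of exactly P distinct subjects (the last group topped up with resampled
## subjects), K sequence rows per subject (with replacement when a subject
## has fewer than K sequences)
epoch_batches <- function(subj_rows, P, K, seed, epoch, strata = NULL) {
  S <- length(subj_rows)
  ord <- with_seed(derive_seed(seed, "epoch-order", epoch),
                   sample.int(S, S))
  ## class-stratified runs interleave the strata so every P-chunk of the
  ## epoch order mixes classes (a single-class batch has no valid triplet)
  if (!is.null(strata)) {
    grp <- split(ord, strata[ord])
    n <- max(lengths(grp))
    mat <- vapply(grp, function(g) c(g, rep(NA_integer_, n - length(g))),
                  integer(n))
    ord <- as.vector(t(mat))
    ord <- ord[!is.na(ord)]
  }
  nb <- ceiling(S / P)
  lapply(seq_len(nb), function(bi) {
    sel <- ord[((bi - 1) * P + 1):min(bi * P, S)]
    if (length(sel) < P) {
      extra <- with_seed(derive_seed(seed, "epoch-fill", epoch, bi),
                         sample(setdiff(seq_len(S), sel), P - length(sel)))
      sel <- c(sel, extra)
    }
    unlist(lapply(seq_along(sel), function(k) {
      rows <- subj_rows[[sel[k]]]
      with_seed(derive_seed(seed, "pick", epoch, bi * 1000L + k),
                if (length(rows) >= K) sample(rows, K)
                else sample(rows, K, replace = TRUE))
    }))
  })
}

#' P x K batch sampler
#'
#' Iterator over training batches: each batch holds exactly `P` distinct
#' subjects with `K` sequences per subject (drawn with replacement when a
#' subject has fewer than `K` sequences). Every subject appears at least
#' once per epoch; epoch order is seeded.
#'
#' @param manifest data frame with a `subject_id` column.
#' @param P subjects per batch (the manifest must contain at least `P`
#'   subjects).
#' @param K sequences per subject.
#' @param seed integer seed.
#' @return list with `next_batch()` (returns manifest row indices),
#'   `reset()`, and `batches_per_epoch`.
#' @export
pk_batch_sampler <- function(manifest, P, K, seed = 1L) {
  subj <- unique(manifest$subject_id)
  if (length(subj) < P)
    stop(sprintf("need at least P = %d subjects, found %d", P, length(subj)))
  subj_rows <- lapply(subj, function(s) which(manifest$subject_id == s))
  bpe <- ceiling(length(subj) / P)
  env <- new.env()
  env$iter <- 0L
  list(
    next_batch = function() {
      env$iter <- env$iter + 1L
      epoch <- (env$iter - 1L) %/% bpe + 1L
      slot <- (env$iter - 1L) %% bpe + 1L
      epoch_batches(subj_rows, P, K, seed, epoch)[[slot]]
    },
    reset = function() env$iter <- 0L,
    batches_per_epoch = bpe)
}

## ---- forward / backward over one batch ----------------------------------

## stack the (already templated) sequences into (128, 128, 2, T*B)
stack_batch <- function(seqs) {
  Tn <- n_frames(seqs[[1]])
  B <- length(seqs)
  X <- array(0, c(128, 128, 2, Tn * B))
  for (b in seq_len(B)) {
    if (n_frames(seqs[[b]]) != Tn) stop("unequal template lengths in batch")
    X[, , , (b - 1) * Tn + seq_len(Tn)] <- seq_frames(seqs[[b]])
  }
  list(X = X, Tn = Tn, B = B)
}

## full cached forward; returns everything needed for the backward pass
forward_train <- function(model, cfg, X, Tn, B, iter) {
  sp <- model$specs
  df <- dsfe_fwd_cached(model$par$dsfe, X, sp$conv)
  hp <- hp_fwd(df$y, cfg$parts)
  c1 <- sp$c1; p <- cfg$parts
  parts <- vector("list", p); heads <- vector("list", p)
  emb <- array(0, c(B, p, cfg$embed_dim))
  logits <- vector("list", p)
  for (j in seq_len(p)) {
    Xj <- aperm(array(hp$F[, j, ], c(c1, Tn, B)), c(2, 1, 3))
    if (!is.null(sp$mtm)) {
      mt <- mtm_fwd_cached(model$par$mtm[[j]], Xj, sp$mtm,
                           model$state$mtm[[j]], training = TRUE,
                           seed = derive_seed(cfg$seed, "dropout", iter, j))
      model$state$mtm[[j]] <- mt$state
      fj <- mt$out
      parts[[j]] <- list(mtm_cache = mt$cache, Xj_dim = dim(Xj))
    } else {
      ## ablation: plain temporal max pooling over the part's frames
      zz <- matrix(Xj, Tn, c1 * B)
      am <- max.col(t(zz), ties.method = "first")
      fj <- matrix(zz[cbind(am, seq_len(c1 * B))], c1, B)
      parts[[j]] <- list(tp_amax = am, Xj_dim = dim(Xj))
    }
    hf <- head_fwd_cached(model$par$head[[j]], fj, model$state$head[[j]],
                          training = TRUE)
    model$state$head[[j]] <- hf$state
    heads[[j]] <- hf$cache
    emb[, j, ] <- t(hf$e_pre)
    logits[[j]] <- hf$logits
  }
  list(model = model, dsfe_cache = df$cache, hp_cache = hp$cache,
       parts = parts, heads = heads, emb = emb, logits = logits,
       Tn = Tn, B = B)
}

backward_train <- function(model, cfg, fw, y, n_class) {
  sp <- model$specs; p <- cfg$parts; c1 <- sp$c1
  Tn <- fw$Tn; B <- fw$B
  lc <- cfg$loss
  tri <- ba_triplet_loss(fw$emb, y, margin = lc$margin, gradient = TRUE)
  l_cro <- 0
  grads <- list(dsfe = NULL, mtm = if (!is.null(sp$mtm)) vector("list", p),
                head = vector("list", p))
  dF <- array(0, c(c1, p, Tn * B))
  for (j in seq_len(p)) {
    ce <- label_smoothing_ce(t(fw$logits[[j]]), y, epsilon = lc$epsilon,
                             gradient = TRUE)
    l_cro <- l_cro + ce$loss / p
    dlogits <- t(ce$grad) * (lc$lambda_cro / p)
    de_pre <- t(matrix(tri$grad[, j, ], B, cfg$embed_dim)) * lc$lambda_tri
    hb <- head_bwd(model$par$head[[j]], fw$heads[[j]], dlogits, de_pre)
    grads$head[[j]] <- hb$grads
    if (!is.null(sp$mtm)) {
      mb <- mtm_bwd(model$par$mtm[[j]], fw$parts[[j]]$mtm_cache, sp$mtm, hb$df)
      grads$mtm[[j]] <- mb$grads
      dXj <- mb$dX
    } else {
      dzz <- matrix(0, Tn, c1 * B)
      dzz[cbind(fw$parts[[j]]$tp_amax, seq_len(c1 * B))] <- as.vector(hb$df)
      dXj <- array(dzz, fw$parts[[j]]$Xj_dim)
    }
    ## dXj (T, c1, B) -> dF (c1, j, (b-1)T+t)
    dF[, j, ] <- matrix(aperm(dXj, c(2, 1, 3)), c1, Tn * B)
  }
  dmap <- hp_bwd(fw$hp_cache, dF)
  db <- dsfe_bwd(model$par$dsfe, fw$dsfe_cache, sp$conv, dmap)
  grads$dsfe <- db$grads
  if (is.null(sp$mtm)) grads$mtm <- NULL
  list(grads = grads, l_tri = tri$loss, l_cro = l_cro,
       n_active = tri$n_active)
}

## prepare one training-ready sequence: length policy + template
train_sequence <- function(seq, cfg, iter, epoch, row_id) {
  s <- apply_length_policy(seq, cfg$min_len, cfg$target_len, mode = "train",
                           seed = derive_seed(cfg$seed, "crop", iter, row_id))
  if (is_rejected(s)) return(s)
  tpl <- cfg$template
  if (!isTRUE(cfg$ablation$sttg) && tpl$method == "sttg") tpl$method <- "none"
  tpl$seed <- cfg$seed
  apply_template(s, tpl, epoch = epoch, seq_id = row_id, training = TRUE)
}

fit_gaitscreen <- function(data, target, cfg, init = NULL, verbose = FALSE) {
  manifest <- data$manifest
  lab_col <- if (target == "subject") "subject_id" else "class"
  if (is.null(manifest[[lab_col]]))
    stop("manifest lacks the '", lab_col, "' column required for target ", target)
  ## admissibility under the length policy
  ok <- vapply(data$sequences, function(s) n_frames(s) >= cfg$min_len, logical(1))
  if (!all(ok)) {
    message(sprintf("excluding %d sequence(s) shorter than %d frames",
                    sum(!ok), cfg$min_len))
    manifest <- manifest[ok, , drop = FALSE]
    data$sequences <- data$sequences[ok]
  }
  labels <- manifest[[lab_col]]
  levels <- sort(unique(labels))
  y <- match(labels, levels)
  n_class <- length(levels)
  if (n_class < 2) stop("training requires at least two distinct labels")

  if (is.null(init)) {
    m0 <- model_init(cfg, n_class)
    model <- list(par = m0$par, state = m0$state, specs = m0$specs)
    adam <- adam_init(m0$par)
    start_iter <- 0L
    log <- data.frame(iteration = integer(), l_tri = numeric(),
                      l_cro = numeric(), l_mul = numeric(), active = integer())
  } else {
    if (!inherits(init, "gaitscreen")) stop("init must be a gaitscreen checkpoint")
    if (!identical(config_hash(cfg), init$config_hash))
      stop("configuration fingerprint mismatch: refusing to resume from this checkpoint")
    model <- list(par = init$par, state = init$state, specs = model_specs(cfg))
    adam <- init$adam
    start_iter <- init$iteration
    log <- init$log
  }

  subj <- unique(manifest$subject_id)
  P <- cfg$subjects_per_batch; K <- cfg$seqs_per_subject
  if (length(subj) < P)
    stop(sprintf("need at least P = %d subjects with admissible sequences", P))
  subj_rows <- lapply(subj, function(s) which(manifest$subject_id == s))
  bpe <- ceiling(length(subj) / P)
  ## screening runs stratify the epoch order by class so batches mix classes
  strata <- if (target == "class")
    vapply(subj, function(s) manifest$class[manifest$subject_id == s][1],
           character(1))
  else NULL

  for (iter in (start_iter + 1L):cfg$iterations) {
    if (cfg$iterations < iter) break
    epoch <- (iter - 1L) %/% bpe + 1L
    slot <- (iter - 1L) %% bpe + 1L
    rows <- epoch_batches(subj_rows, P, K, cfg$seed, epoch, strata)[[slot]]
    seqs <- vector("list", length(rows))
    for (i in seq_along(rows))
      seqs[[i]] <- train_sequence(data$sequences[[rows[i]]], cfg, iter, epoch,
                                  rows[i])
    sb <- stack_batch(seqs)
    fw <- forward_train(model, cfg, sb$X, sb$Tn, sb$B, iter)
    model <- fw$model
    bw <- backward_train(model, cfg, fw, y[rows], n_class)
    l_mul <- combined_loss(max(0, bw$l_tri), max(0, bw$l_cro), cfg$loss)
    if (!is.finite(l_mul)) {
      dump <- file.path(tempdir(), sprintf("gaitscreen-diverged-%d.rds", iter))
      saveRDS(list(iteration = iter, model = model, batch_rows = rows), dump)
      stop(sprintf("non-finite loss at iteration %d; diagnostic dump: %s",
                   iter, dump))
    }
    st <- adam_step(model$par, bw$grads, adam, cfg$lr)
    model$par <- st$par; adam <- st$st
    log <- rbind(log, data.frame(iteration = iter, l_tri = bw$l_tri,
                                 l_cro = bw$l_cro, l_mul = l_mul,
                                 active = bw$n_active))
    if (verbose && iter %% 25 == 0)
      message(sprintf("iter %5d  L_mul %.4f  L_tri %.4f  L_cro %.4f  active %d",
                      iter, l_mul, bw$l_tri, bw$l_cro, bw$n_active))
  }

  structure(list(par = model$par, state = model$state, specs = model$specs,
                 config = cfg, config_hash = config_hash(cfg),
                 target = target, levels = levels,
                 iteration = cfg$iterations, log = log, adam = adam),
            class = "gaitscreen")
}

## ---- evaluation-mode forward --------------------------------------------

## deterministic eval path: length policy in eval mode, template with k = 1
eval_sequence <- function(seq, cfg) {
  s <- apply_length_policy(seq, cfg$min_len, cfg$target_len, mode = "eval")
  if (is_rejected(s)) return(s)
  tpl <- cfg$template
  if (!isTRUE(cfg$ablation$sttg) && tpl$method == "sttg") tpl$method <- "none"
  apply_template(s, tpl, training = FALSE)
}

embed_sequences <- function(object, seqs) {
  cfg <- object$config; sp <- object$specs
  p <- cfg$parts; c1 <- sp$c1; d <- cfg$embed_dim
  n_class <- length(object$levels)
  keep <- c(); rejected <- c()
  embs <- list(); logit_l <- list()
  for (i in seq_along(seqs)) {
    s <- eval_sequence(seqs[[i]], cfg)
    if (is_rejected(s)) { rejected <- c(rejected, i); next }
    keep <- c(keep, i)
    sb <- stack_batch(list(s))
    fmap <- dsfe_fwd_cached(object$par$dsfe, sb$X, sp$conv)$y
    hp <- hp_fwd(fmap, p)
    e <- matrix(0, p, d); lg <- matrix(0, p, n_class)
    for (j in seq_len(p)) {
      Xj <- aperm(array(hp$F[, j, ], c(c1, sb$Tn, 1L)), c(2, 1, 3))
      fj <- if (!is.null(sp$mtm)) {
        mtm_fwd_cached(object$par$mtm[[j]], Xj, sp$mtm,
                       object$state$mtm[[j]], training = FALSE)$out
      } else {
        matrix(apply(Xj, 2, max), c1, 1)
      }
      hf <- head_fwd_cached(object$par$head[[j]], fj, object$state$head[[j]],
                            training = FALSE)
      e[j, ] <- hf$e_pre
      lg[j, ] <- hf$logits
    }
    embs[[length(embs) + 1L]] <- e
    logit_l[[length(logit_l) + 1L]] <- lg
  }
  n <- length(embs)
  emb <- array(0, c(n, p, d)); logits <- array(0, c(n, p, n_class))
  prob <- matrix(0, n, n_class, dimnames = list(NULL, object$levels))
  for (i in seq_len(n)) {
    emb[i, , ] <- embs[[i]]
    logits[i, , ] <- logit_l[[i]]
    pr <- exp(sweep(logit_l[[i]], 1, apply(logit_l[[i]], 1, max)))
    pr <- pr / rowSums(pr)
    prob[i, ] <- colMeans(pr)
  }
  list(emb = emb, logits = logits, prob = prob, kept = keep,
       rejected = rejected)
}

#' Screening score of gait sequences
#'
#' Scalar score for the impaired class. The default is the softmax
#' probability of the impaired class averaged over the per-part classifiers;
#' the alternative scores a sequence by the negative Euclidean distance of
#' its embedding to the healthy-class prototype built from `ref_data`.
#'
#' @param object a fitted two-class (`target = "class"`) `"gaitscreen"` model.
#' @param data a `gait_data` object or list of sequences to score.
#' @param method `"softmax"` (default) or `"prototype"`.
#' @param ref_data reference `gait_data` (training split) used to build the
#'   healthy prototype when `method = "prototype"`.
#' @param ensemble_k `TRUE` to average the softmax score over all `M`
#'   systematic template offsets instead of the single deterministic offset
#'   `k = 1` (so every frame contributes), or an integer vector of offsets;
#'   deterministic either way. See [predict.gaitscreen()].
#' @return numeric vector of scores (higher = more impaired); softmax scores
#'   lie in \[0, 1\].
#' @export
screening_score <- function(object, data, method = c("softmax", "prototype"),
                            ref_data = NULL, ensemble_k = FALSE) {
  method <- match.arg(method)
  if (object$target != "class")
    stop("screening_score requires a model trained with target = 'class'")
  if (method == "softmax")
    return(as.numeric(predict(object, data, type = "score",
                              ensemble_k = ensemble_k)))
  if (is.null(ref_data)) stop("method = 'prototype' requires ref_data")
  ref_emb <- predict(object, ref_data, type = "embedding")
  healthy <- ref_data$manifest$class == "healthy"
  proto <- apply(ref_emb[healthy, , , drop = FALSE], c(2, 3), mean)
  emb <- predict(object, data, type = "embedding")
  vapply(seq_len(dim(emb)[1]), function(i)
    -sqrt(sum((emb[i, , ] - proto)^2)), numeric(1))
}

## ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameters, optimiser state, running statistics,
#' iteration counter and the configuration fingerprint; a JSON sidecar
#' records the fingerprint, seed and iteration for quick inspection. Loading
#' verifies the fingerprint, and [gaitscreen()] refuses to resume from a
#' checkpoint whose fingerprint does not match its configuration.
#'
#' @param object a fitted `"gaitscreen"` model.
#' @param path file path for the checkpoint (`.rds`).
#' @return `save_gaitscreen` returns `path` invisibly; `load_gaitscreen`
#'   returns the model.
#' @export
save_gaitscreen <- function(object, path) {
  saveRDS(object, path)
  jsonlite::write_json(list(config_hash = object$config_hash,
                            seed = object$config$seed,
                            iteration = object$iteration,
                            target = object$target),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gaitscreen
#' @export
load_gaitscreen <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "gaitscreen")) stop("not a gaitscreen checkpoint")
  if (!identical(object$config_hash, config_hash(object$config)))
    stop("checkpoint fingerprint does not match its stored configuration")
  object
}
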