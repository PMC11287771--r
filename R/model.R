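## The fitting interface: `gaitscreen()` trains the part-based
## spatio-temporal network on a prepared gait dataset and returns a classed
## model object with the usual methods (print, summary, coef, predict, plot).

#' Model and training configuration
#'
#' Defaults follow the reference architecture: base width 32 (channel chain
#' 2 -> 32/32/64/64/192/192), 16 horizontal parts, 128-dim per-part
#' embeddings, STTG template sampling with M = 4, P x K = 4 x 6 batches,
#' triplet margin 0.2 with loss weights (1.0, 0.2), Adam at learning rate
#' 1e-4. Tiny test models shrink `base_channels`, `parts`, `embed_dim` and
#' `iterations`.
#'
#' @param base_channels DSFE base width (reference: 32).
#' @param parts number of horizontal parts p; must divide the 16-row output
#'   feature map.
#' @param embed_dim per-part embedding width d.
#' @param template a [template_spec()].
#' @param ds_placement DS-Conv2d placement flags, see [conv_stack_spec()].
#' @param leaky_slope LeakyReLU slope for all activations.
#' @param attention_reduction,dropout,attention_sigmoid,recurrent,use_frame_branch,use_attention,tp_mode
#'   MTM options, see [mtm_spec()].
#' @param loss a [loss_config()].
#' @param subjects_per_batch,seqs_per_subject P and K of the batch sampler.
#' @param lr Adam learning rate.
#' @param iterations number of training iterations.
#' @param min_len,target_len sequence-length policy, see
#'   [apply_length_policy()].
#' @param seed master seed; every random stream (initialisation, batch
#'   order, template offsets, crops, dropout) derives from it.
#' @param ablation named logical list with entries `sttg`, `dsfe`, `mta`
#'   switching the three components (all `TRUE` by default; all `FALSE`
#'   reproduces the plain block + horizontal-pooling + temporal-max
#'   baseline).
#' @return object of class `"gaitscreen_config"`.
#' @export
gaitscreen_config <- function(base_channels = 32L, parts = 16L,
                              embed_dim = 128L,
                              template = template_spec(method = "sttg", M = 4L),
                              ds_placement = list(block1 = c(FALSE, TRUE),
                                                  block2 = c(FALSE, FALSE),
                                                  block3 = c(FALSE, FALSE)),
                              leaky_slope = 0.01,
                              attention_reduction = 16L, dropout = 0.2,
                              attention_sigmoid = FALSE,
                              recurrent = "bilstm", use_frame_branch = TRUE,
                              use_attention = TRUE, tp_mode = "max",
                              loss = loss_config(),
                              subjects_per_batch = 4L, seqs_per_subject = 6L,
                              lr = 1e-4, iterations = 10000L,
                              min_len = 15L, target_len = 80L,
                              seed = 1L,
                              ablation = list(sttg = TRUE, dsfe = TRUE,
                                              mta = TRUE)) {
  if (subjects_per_batch < 2) stop("subjects_per_batch must be >= 2")
  if (seqs_per_subject < 1) stop("seqs_per_subject must be >= 1")
  if (16L %% parts != 0) stop("parts must divide the feature height 16")
  ablation <- utils::modifyList(list(sttg = TRUE, dsfe = TRUE, mta = TRUE),
                                as.list(ablation))
  cfg <- list(base_channels = as.integer(base_channels),
              parts = as.integer(parts), embed_dim = as.integer(embed_dim),
              template = template, ds_placement = ds_placement,
              leaky_slope = leaky_slope,
              attention_reduction = as.integer(attention_reduction),
              dropout = dropout, attention_sigmoid = attention_sigmoid,
              recurrent = recurrent, use_frame_branch = use_frame_branch,
              use_attention = use_attention, tp_mode = tp_mode,
              loss = loss,
              subjects_per_batch = as.integer(subjects_per_batch),
              seqs_per_subject = as.integer(seqs_per_subject),
              lr = lr, iterations = as.integer(iterations),
              min_len = as.integer(min_len), target_len = as.integer(target_len),
              seed = as.integer(seed), ablation = ablation)
  class(cfg) <- "gaitscreen_config"
  cfg
}

## configuration fingerprint; iteration count excluded so a checkpoint can be
## resumed to a larger total
config_hash <- function(cfg) {
  cfg$iterations <- NULL
  hash_obj(unclass(cfg))
}

## derived architecture pieces
model_specs <- function(cfg) {
  conv <- conv_stack_spec(cfg$base_channels, cfg$ds_placement,
                          cfg$leaky_slope, dsfe = isTRUE(cfg$ablation$dsfe))
  c1 <- conv$out_channels
  mtm <- if (isTRUE(cfg$ablation$mta))
    mtm_spec(c1, attention_reduction = cfg$attention_reduction,
             dropout_rate = cfg$dropout, leaky_slope = cfg$leaky_slope,
             use_frame_branch = cfg$use_frame_branch,
             recurrent = cfg$recurrent, use_attention = cfg$use_attention,
             attention_sigmoid = cfg$attention_sigmoid, tp_mode = cfg$tp_mode)
  else NULL
  list(conv = conv, mtm = mtm, c1 = c1,
       head_in = if (is.null(mtm)) c1 else mtm$c2)
}

model_init <- function(cfg, n_class) {
  sp <- model_specs(cfg)
  seed <- derive_seed(cfg$seed, "init")
  par <- list(dsfe = dsfe_init(sp$conv, derive_seed(seed, "dsfe")))
  state <- list(mtm = NULL, head = vector("list", cfg$parts))
  if (!is.null(sp$mtm)) {
    par$mtm <- lapply(seq_len(cfg$parts), function(j)
      mtm_init(sp$mtm, derive_seed(seed, "mtm", j)))
    state$mtm <- lapply(seq_len(cfg$parts), function(j) mtm_state_init(sp$mtm))
  }
  par$head <- lapply(seq_len(cfg$parts), function(j)
    head_init(sp$head_in, cfg$embed_dim, n_class, derive_seed(seed, "head", j)))
  for (j in seq_len(cfg$parts)) state$head[[j]] <- head_state_init(cfg$embed_dim)
  list(par = par, state = state, specs = sp)
}

#' Fit the gait recognition / screening model
#'
#' Trains the part-based spatio-temporal network: sequence-length policy ->
#' temporal template -> depth-wise spatial feature extractor -> horizontal
#' partition pooling -> per-part multi-scale temporal aggregation -> per-part
#' FC + BN embedding head, optimised with the combined batch-all triplet +
#' label-smoothing cross-entropy loss via Adam. All computations derive from
#' `config$seed`, so a fit is exactly reproducible.
#'
#' @param data a `gait_data` object (see [prepare_gait_data()]).
#' @param target label used for both losses: `"subject"` (identification) or
#'   `"class"` (two-class cognitive-impairment screening).
#' @param config a [gaitscreen_config()].
#' @param init optional checkpoint (a fitted `"gaitscreen"` object) to resume
#'   from; its configuration fingerprint must match `config`.
#' @param verbose print the loss every 25 iterations.
#' @return object of class `"gaitscreen"`.
#' @seealso [predict.gaitscreen()], [screening_score()], [save_gaitscreen()]
#' @export
gaitscreen <- function(data, target = c("subject", "class"),
                       config = gaitscreen_config(), init = NULL,
                       verbose = FALSE) {
  target <- match.arg(target)
  fit_gaitscreen(data, target, config, init, verbose)
}

#' @export
print.gaitscreen <- function(x, ...) {
  cat("Part-based spatio-temporal gait model\n")
  cat(sprintf("  target: %s (%d classes)   parts: %d   embed dim: %d\n",
              x$target, length(x$levels), x$config$parts, x$config$embed_dim))
  cat(sprintf("  base width: %d (c1 = %d)   template: %s (M = %d)\n",
              x$config$base_channels, x$specs$c1,
              x$config$template$method, x$config$template$M))
  cat(sprintf("  iterations: %d   final L_mul: %.4f\n",
              x$iteration, utils::tail(x$log$l_mul, 1)))
  invisible(x)
}

#' @export
summary.gaitscreen <- function(object, ...) {
  cat("Architecture (depth-wise part feature extractor):\n")
  print(describe_conv_stack(object$specs$conv), row.names = FALSE)
  cat(sprintf("\nMTA: %s%s, attention %s, temporal pooling: %s\n",
              if (isTRUE(object$config$ablation$mta)) object$config$recurrent
              else "disabled (temporal max pooling only)",
              if (isTRUE(object$config$ablation$mta) && object$config$use_frame_branch)
                " + frame-level branch" else "",
              if (isTRUE(object$config$ablation$mta) && object$config$use_attention)
                "on" else "off",
              object$config$tp_mode %||% "max"))
  cat(sprintf("Losses: lambda_tri = %g, lambda_cro = %g, margin = %g, epsilon = %g\n",
              object$config$loss$lambda_tri, object$config$loss$lambda_cro,
              object$config$loss$margin, object$config$loss$epsilon))
  n <- nrow(object$log)
  if (n > 0) {
    w <- max(1, n - 24):n
    cat(sprintf("Loss (last 25 iters): L_mul %.4f, L_tri %.4f, L_cro %.4f, active triplets %.1f\n",
                mean(object$log$l_mul[w]), mean(object$log$l_tri[w]),
                mean(object$log$l_cro[w]), mean(object$log$active[w])))
  }
  invisible(object)
}

#' @export
coef.gaitscreen <- function(object, ...) object$par

#' @export
plot.gaitscreen <- function(x, ...) {
  graphics::plot(x$log$iteration, x$log$l_mul, type = "l",
                 xlab = "iteration", ylab = "loss",
                 main = "training loss", ...)
  graphics::lines(x$log$iteration, x$log$l_tri, col = "steelblue")
  graphics::lines(x$log$iteration, x$log$l_cro, col = "indianred")
  graphics::legend("topright", c("L_mul", "L_tri", "L_cro"),
                   col = c("black", "steelblue", "indianred"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict from a fitted gait model
#'
#' @param object a fitted `"gaitscreen"` model.
#' @param newdata a `gait_data` object, a list of `dual_channel_sequence`s,
#'   or a single sequence.
#' @param type `"embedding"` (n x p x d pre-BN part embeddings, the unit
#'   compared by the triplet loss and by ranking), `"logits"` (n x p x C),
#'   `"prob"` (n x C softmax averaged over parts) or `"score"` (positive-class
#'   probability; screening models only).
#' @param ensemble_k `TRUE` to average the prediction over all `M` systematic
#'   template offsets (instead of the single deterministic offset `k = 1`),
#'   so every frame of the sequence contributes, or an integer vector of
#'   offsets to average over; deterministic either way.
#' @param ... unused.
#' @return see `type`. Sequences rejected by the length policy are reported
#'   via the `"rejected"` attribute and excluded from the output rows.
#' @export
predict.gaitscreen <- function(object, newdata,
                               type = c("embedding", "logits", "prob", "score"),
                               ensemble_k = FALSE, ...) {
  type <- match.arg(type)
  seqs <- if (inherits(newdata, "gait_data")) newdata$sequences
  else if (inherits(newdata, "dual_channel_sequence")) list(newdata)
  else newdata
  if (!isFALSE(ensemble_k) &&
      object$config$template$method %in% c("sttg", "equidistant")) {
    M <- object$config$template$M
    ks <- if (isTRUE(ensemble_k)) seq_len(M) else as.integer(ensemble_k)
    if (any(ks < 1 | ks > M)) stop("ensemble offsets must lie in 1..M")
    res <- NULL
    for (k in ks) {
      ok <- object
      ok$config$template$k <- k
      rk <- embed_sequences(ok, seqs)
      if (is.null(res)) res <- rk
      else { res$emb <- res$emb + rk$emb; res$logits <- res$logits + rk$logits
             res$prob <- res$prob + rk$prob }
    }
    nk <- length(ks)
    res$emb <- res$emb / nk; res$logits <- res$logits / nk
    res$prob <- res$prob / nk
  } else {
    res <- embed_sequences(object, seqs)
  }
  out <- switch(type,
                embedding = res$emb,
                logits = res$logits,
                prob = res$prob,
                score = {
                  if (ncol(res$prob) != 2)
                    stop("score predictions require a two-class model")
                  pos <- if ("impaired" %in% object$levels)
                    which(object$levels == "impaired") else 2L
                  res$prob[, pos]
                })
  attr(out, "rejected") <- res$rejected
  out
}
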