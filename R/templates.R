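## Temporal template generators. The input sequence is grouped into
## consecutive blocks of M frames; each generator emits floor(t/M) template
## frames (the trailing partial group is dropped). The short-term temporal
## template generator (STTG) performs systematic random sampling: one offset
## k, drawn uniformly from 1..M once per sequence per training epoch, selects
## the k-th frame of every group, so the selected global indices are all
## congruent to k-1 (mod M). The comparison generators are the gait energy
## image (per-group pixel mean), equidistant sampling (fixed k = 1) and
## simple random sampling (independent offset per group).

#' Template generator specification
#'
#' @param method one of `"sttg"`, `"gei"`, `"equidistant"`,
#'   `"simple_random"`, `"none"`.
#' @param M group size (>= 1); the template keeps one frame per M input frames.
#' @param k fixed selection offset in 1..M, or `NULL` to draw it per epoch
#'   (training) / use 1 (evaluation).
#' @param seed base seed for the per-epoch offset draws.
#' @return object of class `"template_spec"`.
#' @export
template_spec <- function(method = c("sttg", "gei", "equidistant",
                                     "simple_random", "none"),
                          M = 4L, k = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot_scalar(M, "M", positive = TRUE)
  if (!is.null(k) && (k < 1 || k > M)) stop("k must lie in 1..M")
  structure(list(method = method, M = as.integer(M), k = k,
                 seed = as.integer(seed)), class = "template_spec")
}

#' Draw the systematic-sampling offset for one epoch
#'
#' Uniform draw of `k` from `{1, ..., M}`; redrawn once per sequence per
#' training epoch.
#'
#' @param M group size (>= 1).
#' @param seed integer seed identifying the (sequence, epoch) draw.
#' @return integer `k` in 1..M.
#' @export
draw_k <- function(M, seed) {
  if (!is.numeric(M) || M < 1) stop("M must be >= 1")
  if (M == 1) return(1L)
  with_seed(seed, sample.int(as.integer(M), 1L))
}

## frame-index view of a sequence-like object
template_frame_count <- function(seq) {
  if (inherits(seq, "dual_channel_sequence")) n_frames(seq) else dim(seq)[length(dim(seq))]
}

select_template_frames <- function(seq, idx) {
  if (inherits(seq, "dual_channel_sequence"))
    return(reindex_seq(seq, seq$frame_idx[idx]))
  nd <- length(dim(seq))
  ix <- rep(list(quote(expr = )), nd); ix[[nd]] <- idx
  do.call(`[`, c(list(seq), ix, list(drop = FALSE)))
}

#' Systematic random sampling (STTG)
#'
#' Keeps the `k`-th frame of every complete group of `M` consecutive frames:
#' output frame `i` (1-based) is input frame `(i - 1) * M + k`.
#'
#' @param seq a `dual_channel_sequence` or an array whose last dimension
#'   indexes frames.
#' @param M group size; the sequence must contain at least `M` frames.
#' @param k offset in 1..M.
#' @return template sequence with `floor(t / M)` frames, same type as `seq`.
#' @examples
#' x <- array(1:8, c(1, 1, 8))
#' sttg_sample(x, M = 4, k = 2)[1, 1, ]   # frames 2 and 6
#' @export
sttg_sample <- function(seq, M, k) {
  t <- template_frame_count(seq)
  if (M < 1) stop("M must be >= 1")
  if (k < 1 || k > M) stop("k must lie in 1..M")
  if (t < M) stop(sprintf("sequence too short: %d frames < group size %d", t, M))
  g <- t %/% M
  select_template_frames(seq, (seq_len(g) - 1L) * as.integer(M) + as.integer(k))
}

#' Equidistant sampling
#'
#' Deterministic template: the first frame of every group, identical to
#' [sttg_sample()] with `k = 1`.
#' @inheritParams sttg_sample
#' @export
equidistant_sample <- function(seq, M) sttg_sample(seq, M, k = 1L)

#' Simple random sampling
#'
#' One independent uniform offset per group, so adjacent global selections
#' are possible (unlike systematic sampling).
#' @inheritParams sttg_sample
#' @param seed seed for the per-group draws.
#' @export
simple_random_sample <- function(seq, M, seed = 1L) {
  t <- template_frame_count(seq)
  if (t < M) stop(sprintf("sequence too short: %d frames < group size %d", t, M))
  g <- t %/% M
  ks <- with_seed(seed, sample.int(as.integer(M), g, replace = TRUE))
  select_template_frames(seq, (seq_len(g) - 1L) * as.integer(M) + ks)
}

#' Gait energy image template
#'
#' Replaces every group of `M` frames by its pixelwise mean, trading temporal
#' information for compactness.
#' @inheritParams sttg_sample
#' @return array (or `dual_channel_sequence` with double storage) of
#'   `floor(t / M)` averaged frames.
#' @export
gei_template <- function(seq, M) {
  t <- template_frame_count(seq)
  if (t < M) stop(sprintf("sequence too short: %d frames < group size %d", t, M))
  g <- t %/% M
  if (inherits(seq, "dual_channel_sequence")) {
    fr <- seq_frames(seq)
    out <- array(0, c(128, 128, 2, g))
    for (i in seq_len(g))
      out[, , , i] <- apply(fr[, , , (i - 1) * M + seq_len(M), drop = FALSE],
                            1:3, mean)
    res <- structure(list(data = out, frame_idx = seq_len(g), meta = seq$meta),
                     class = "dual_channel_sequence")
    return(res)
  }
  d <- dim(seq); nd <- length(d)
  od <- d; od[nd] <- g
  out <- array(0, od)
  ixo <- rep(list(quote(expr = )), nd)
  for (i in seq_len(g)) {
    sel <- select_template_frames(seq, (i - 1) * M + seq_len(M))
    ixo[[nd]] <- i
    out <- do.call(`[<-`, c(list(out), ixo, list(apply(sel, seq_len(nd - 1), mean))))
  }
  out
}

## resolve a template spec into a concrete frame selection for one sequence
apply_template <- function(seq, spec, epoch = 1L, seq_id = 1L, training = TRUE) {
  if (spec$method == "none") return(seq)
  if (spec$method == "gei") return(gei_template(seq, spec$M))
  k <- if (!is.null(spec$k)) spec$k
  else if (spec$method == "equidistant" || !training) 1L
  else draw_k(spec$M, derive_seed(spec$seed, "k", epoch, seq_id))
  switch(spec$method,
         sttg = sttg_sample(seq, spec$M, k),
         equidistant = equidistant_sample(seq, spec$M),
         simple_random = simple_random_sample(
           seq, spec$M, seed = derive_seed(spec$seed, "srs", epoch, seq_id)))
}
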