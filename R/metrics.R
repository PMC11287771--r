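## Evaluation metrics: identification (rank-k, mAP, mINP) and two-class
## screening (tie-corrected ROC AUC with bootstrap CI, Gini coefficient,
## maximum Kolmogorov-Smirnov statistic).

#' Ranking task container
#'
#' @param probe_emb probe embeddings: `n x p x d` array or `n x m` matrix.
#' @param probe_labels identity labels of the probes.
#' @param gallery_emb,gallery_labels gallery embeddings and labels.
#' @param probe_view,gallery_view optional view tags; when given, gallery
#'   entries sharing a probe's view are excluded from that probe's ranking.
#' @param distance `"flat"` (Euclidean on the flattened part-by-dim matrix,
#'   default) or `"mean_part"` (mean of per-part Euclidean distances).
#' @return object of class `"ranking_task"` with the probe-by-gallery
#'   distance matrix.
#' @export
ranking_task <- function(probe_emb, probe_labels, gallery_emb, gallery_labels,
                         probe_view = NULL, gallery_view = NULL,
                         distance = c("flat", "mean_part")) {
  distance <- match.arg(distance)
  flat <- function(e) if (is.matrix(e)) e else matrix(e, dim(e)[1], prod(dim(e)[-1]))
  if (length(gallery_labels) == 0) stop("gallery must be non-empty")
  if (distance == "flat" || is.matrix(probe_emb)) {
    P <- flat(probe_emb); G <- flat(gallery_emb)
    D <- sqrt(pmax(outer(rowSums(P^2), rowSums(G^2), `+`) - 2 * tcrossprod(P, G), 0))
  } else {
    p <- dim(probe_emb)[2]
    D <- 0
    for (j in seq_len(p)) {
      Pj <- matrix(probe_emb[, j, ], dim(probe_emb)[1], dim(probe_emb)[3])
      Gj <- matrix(gallery_emb[, j, ], dim(gallery_emb)[1], dim(gallery_emb)[3])
      D <- D + sqrt(pmax(outer(rowSums(Pj^2), rowSums(Gj^2), `+`) -
                           2 * tcrossprod(Pj, Gj), 0)) / p
    }
  }
  structure(list(D = D, probe_labels = probe_labels,
                 gallery_labels = gallery_labels,
                 probe_view = probe_view, gallery_view = gallery_view),
            class = "ranking_task")
}

## per-probe candidate order (stable: ties keep gallery index order)
probe_order <- function(task, i) {
  keep <- rep(TRUE, length(task$gallery_labels))
  if (!is.null(task$probe_view) && !is.null(task$gallery_view))
    keep <- task$gallery_view != task$probe_view[i]
  idx <- which(keep)
  if (length(idx) == 0) return(integer(0))
  idx[order(task$D[i, idx], method = "radix")]   # stable: ties keep index order
}

#' Rank-k identification accuracy
#'
#' Percentage of probes whose `k` nearest gallery entries contain at least
#' one entry with the probe's label. Probes with no valid gallery candidate
#' (after view exclusion) are excluded and counted.
#'
#' @param task a [ranking_task()].
#' @param k neighbourhood size (>= 1).
#' @return percentage in \[0, 100\] with attribute `"excluded"`.
#' @export
rank_k <- function(task, k = 1L) {
  if (k < 1) stop("k must be >= 1")
  hits <- 0L; valid <- 0L; excluded <- 0L
  for (i in seq_along(task$probe_labels)) {
    ord <- probe_order(task, i)
    if (length(ord) == 0) { excluded <- excluded + 1L; next }
    valid <- valid + 1L
    top <- ord[seq_len(min(k, length(ord)))]
    if (any(task$gallery_labels[top] == task$probe_labels[i])) hits <- hits + 1L
  }
  structure(100 * hits / max(1L, valid), excluded = excluded)
}

#' Mean average precision and mean inverse negative penalty
#'
#' For each probe, AP is the mean over its relevant gallery items of the
#' precision at that item's rank; INP is the number of relevant items divided
#' by the rank of the last relevant item. Probes without any same-label
#' gallery item are excluded.
#'
#' @param task a [ranking_task()].
#' @return list `(map, minp, excluded)`; `map` is a percentage.
#' @export
map_minp <- function(task) {
  aps <- c(); inps <- c(); excluded <- 0L
  for (i in seq_along(task$probe_labels)) {
    ord <- probe_order(task, i)
    rel <- task$gallery_labels[ord] == task$probe_labels[i]
    if (!any(rel)) { excluded <- excluded + 1L; next }
    rk <- which(rel)
    prec <- seq_along(rk) / rk
    aps <- c(aps, mean(prec))
    inps <- c(inps, length(rk) / max(rk))
  }
  list(map = 100 * mean(aps), minp = mean(inps), excluded = excluded)
}

check_scores <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  if (!all(c(0, 1) %in% lab)) stop("both classes must be present")
  lab
}

## positive class: "impaired" when present, else the second factor level /
## the value 1 / TRUE
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  f <- as.factor(labels)
  pos <- if ("impaired" %in% levels(f)) "impaired" else levels(f)[nlevels(f)]
  as.integer(f == pos)
}

#' ROC AUC (tie-corrected) with optional bootstrap confidence interval
#'
#' The area under the receiver operating characteristic computed as the
#' tie-corrected rank statistic: the probability that a random positive
#' outscores a random negative, with ties counted half. The optional 95%
#' confidence interval uses a stratified percentile bootstrap.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels; the positive class is `"impaired"`, `TRUE`,
#'   or `1` (for factors without an `"impaired"` level, the last level).
#' @param ci compute a bootstrap confidence interval.
#' @param reps bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return the AUC, or (with `ci = TRUE`) a list `(auc, ci, reps, level)`.
#' @export
roc_auc <- function(scores, labels, ci = FALSE, reps = 2000L, level = 0.95,
                    seed = 1L) {
  lab <- check_scores(scores, labels)
  auc <- auc_rank(scores, lab)
  if (!ci) return(auc)
  pos <- which(lab == 1); neg <- which(lab == 0)
  boots <- with_seed(seed, vapply(seq_len(reps), function(r) {
    ip <- sample(pos, length(pos), replace = TRUE)
    ineg <- sample(neg, length(neg), replace = TRUE)
    auc_rank(c(scores[ip], scores[ineg]),
             c(rep(1L, length(ip)), rep(0L, length(ineg))))
  }, numeric(1)))
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(auc = auc, ci = qs, reps = reps, level = level)
}

auc_rank <- function(scores, lab) {
  r <- rank(scores)           # midranks handle ties (half credit)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gini coefficient (accuracy ratio) of a score ordering
#'
#' `Gini = 2 * AUC - 1`, computed from the same tie-corrected AUC as
#' [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return the Gini coefficient in \[-1, 1\].
#' @export
gini_coefficient <- function(scores, labels) {
  2 * roc_auc(scores, labels) - 1
}

#' Maximum Kolmogorov-Smirnov statistic of a score set
#'
#' Largest absolute difference between the empirical score CDFs of the two
#' classes, evaluated at all observed scores.
#'
#' @inheritParams roc_auc
#' @return statistic in \[0, 1\].
#' @export
max_ks <- function(scores, labels) {
  lab <- check_scores(scores, labels)
  xs <- sort(unique(scores))
  f1 <- vapply(xs, function(x) mean(scores[lab == 1] <= x), numeric(1))
  f0 <- vapply(xs, function(x) mean(scores[lab == 0] <= x), numeric(1))
  max(abs(f1 - f0))
}

#' Export a ROC curve
#'
#' Writes the threshold sweep as CSV (`threshold`, `fpr`, `tpr`; thresholds
#' descending, curve from (0, 0) to (1, 1)) plus a JSON summary with AUC,
#' Gini and max K-S. A score is called positive when `score >= threshold`.
#'
#' @inheritParams roc_auc
#' @param path output CSV path, or `NULL` to skip writing; the JSON summary
#'   is written next to it as `<path>.json`.
#' @return the curve data frame, invisibly.
#' @export
export_roc <- function(scores, labels, path = NULL) {
  lab <- check_scores(scores, labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & lab == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & lab == 0) / n0, numeric(1))
  curve <- data.frame(threshold = th, fpr = fpr, tpr = tpr)
  if (!is.null(path)) {
    write.csv(curve, path, row.names = FALSE)
    jsonlite::write_json(list(auc = roc_auc(scores, lab),
                              gini = gini_coefficient(scores, lab),
                              max_ks = max_ks(scores, lab),
                              n_pos = n1, n_neg = n0),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(curve)
}
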