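## Training objectives: separate batch-all (BA+) triplet loss, label-smoothing
## cross-entropy, and their weighted combination L_mul = lambda_tri * L_tri +
## lambda_cro * L_cro.

#' Loss configuration
#'
#' @param lambda_tri weight of the triplet loss (default 1.0).
#' @param lambda_cro weight of the cross-entropy loss (default 0.2).
#' @param margin triplet margin (>= 0, default 0.2).
#' @param epsilon label-smoothing mass in \[0, 1) (default 0.1).
#' @return object of class `"loss_config"`.
#' @export
loss_config <- function(lambda_tri = 1.0, lambda_cro = 0.2, margin = 0.2,
                        epsilon = 0.1) {
  stopifnot_scalar(lambda_tri, "lambda_tri", nonneg = TRUE)
  stopifnot_scalar(lambda_cro, "lambda_cro", nonneg = TRUE)
  stopifnot_scalar(margin, "margin", nonneg = TRUE)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  structure(list(lambda_tri = lambda_tri, lambda_cro = lambda_cro,
                 margin = margin, epsilon = epsilon, distance = "euclidean"),
            class = "loss_config")
}

## BA+ triplet loss for one part: emb (n x d), labels length n.
## Returns loss, active count and (optionally) gradient w.r.t. emb.
ba_triplet_part <- function(emb, labels, margin, gradient = FALSE) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(emb), 0)
  D <- sqrt(D2)
  coefD <- if (gradient) matrix(0, n, n) else NULL
  total <- 0; n_active <- 0L; n_triples <- 0L
  rows <- vector("list", n)
  for (a in seq_len(n)) {
    pos <- which(labels == labels[a]); pos <- pos[pos != a]
    neg <- which(labels != labels[a])
    if (length(pos) == 0 || length(neg) == 0) next
    hin <- outer(D[a, pos], D[a, neg], function(dp, dn) dp - dn + margin)
    act <- hin > 0
    n_triples <- n_triples + length(hin)
    n_active <- n_active + sum(act)
    total <- total + sum(hin[act])
    if (gradient && any(act)) {
      rows[[a]] <- list(a = a, pos = pos, neg = neg,
                        wp = rowSums(act), wn = colSums(act))
    }
  }
  loss <- if (n_active > 0) total / n_active else 0
  if (!gradient) return(list(loss = loss, n_active = n_active,
                             n_triples = n_triples))
  grad <- emb * 0
  if (n_active > 0) {
    for (r in rows) {
      if (is.null(r)) next
      coefD[r$a, r$pos] <- coefD[r$a, r$pos] + r$wp / n_active
      coefD[r$a, r$neg] <- coefD[r$a, r$neg] - r$wn / n_active
    }
    ## dL/dD[i,j] accumulated; dD[i,j]/d emb_i = (e_i - e_j) / D[i,j]
    Cs <- coefD + t(coefD)
    Dsafe <- D; Dsafe[Dsafe < 1e-12] <- Inf
    Wd <- Cs / Dsafe
    grad <- (emb * rowSums(Wd)) - Wd %*% emb
  }
  list(loss = loss, n_active = n_active, n_triples = n_triples, grad = grad)
}

#' Separate batch-all (BA+) triplet loss
#'
#' Computed independently per part and averaged over parts. Per part, the
#' hinge `max(0, d(a, p) - d(a, n) + margin)` is evaluated over all valid
#' (anchor, positive, negative) triples of the batch and averaged over the
#' triples with strictly positive hinge (the "+" in BA+); a part with no
#' active triple contributes 0. Distances are Euclidean.
#'
#' @param emb embeddings: `n x p x d` array, or `n x d` matrix (treated as a
#'   single part).
#' @param labels length-n vector of identity (or class) labels.
#' @param margin triplet margin (default 0.2).
#' @param gradient also return the gradient w.r.t. `emb`.
#' @return list with `loss`, `n_active` (count of active triplets summed over
#'   parts), `n_triples`, and optionally `grad` (same shape as `emb`).
#' @export
ba_triplet_loss <- function(emb, labels, margin = 0.2, gradient = FALSE) {
  if (is.matrix(emb)) dim(emb) <- c(nrow(emb), 1L, ncol(emb))
  n <- dim(emb)[1]; p <- dim(emb)[2]
  if (length(labels) != n) stop("labels must match the number of embeddings")
  if (n < 2) stop("at least 2 embeddings are required")
  if (length(unique(labels)) < 2) {
    warning("batch contains a single label: no valid negatives, loss is 0")
    out <- list(loss = 0, n_active = 0L, n_triples = 0L)
    if (gradient) out$grad <- emb * 0
    return(out)
  }
  loss <- 0; n_active <- 0L; n_triples <- 0L
  grad <- if (gradient) emb * 0 else NULL
  for (j in seq_len(p)) {
    pj <- ba_triplet_part(matrix(emb[, j, ], n, dim(emb)[3]), labels, margin,
                          gradient)
    loss <- loss + pj$loss / p
    n_active <- n_active + pj$n_active
    n_triples <- n_triples + pj$n_triples
    if (gradient) grad[, j, ] <- pj$grad / p
  }
  out <- list(loss = loss, n_active = n_active, n_triples = n_triples)
  if (gradient) out$grad <- grad
  out
}

#' Label-smoothing cross-entropy
#'
#' Cross-entropy against the smoothed target that places `1 - epsilon` on the
#' true class and `epsilon / (C - 1)` on each other class, averaged over the
#' batch.
#'
#' @param logits `n x C` matrix of unnormalised scores.
#' @param labels integer class indices in `1..C` (or a factor).
#' @param epsilon smoothing mass in \[0, 1).
#' @param gradient also return the gradient w.r.t. `logits`.
#' @return scalar loss, or a list `(loss, grad)` when `gradient = TRUE`.
#' @export
label_smoothing_ce <- function(logits, labels, epsilon = 0.1, gradient = FALSE) {
  n <- nrow(logits); C <- ncol(logits)
  if (C < 2) stop("at least 2 classes are required")
  if (is.factor(labels)) labels <- as.integer(labels)
  if (any(labels < 1 | labels > C)) stop("labels must lie in 1..C")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  mx <- apply(logits, 1, max)
  ls <- logits - mx
  lse <- log(rowSums(exp(ls)))
  logp <- ls - lse
  q <- matrix(epsilon / (C - 1), n, C)
  q[cbind(seq_len(n), labels)] <- 1 - epsilon
  loss <- -sum(q * logp) / n
  if (!gradient) return(loss)
  soft <- exp(logp)
  list(loss = loss, grad = (soft - q) / n)
}

#' Combined multi-loss
#'
#' `L_mul = lambda_tri * L_tri + lambda_cro * L_cro` with the default weights
#' `lambda_tri = 1.0`, `lambda_cro = 0.2`.
#'
#' @param l_tri triplet loss value (>= 0).
#' @param l_cro cross-entropy loss value (>= 0).
#' @param config a [loss_config()].
#' @return scalar combined loss.
#' @export
combined_loss <- function(l_tri, l_cro, config = loss_config()) {
  stopifnot_scalar(l_tri, "l_tri", nonneg = TRUE)
  stopifnot_scalar(l_cro, "l_cro", nonneg = TRUE)
  config$lambda_tri * l_tri + config$lambda_cro * l_cro
}
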