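## Shared fixtures and independent oracles. Fixtures are generated in code
## (no stored data) and cached for the test session.

fixture_env <- new.env()

## small 6-subject cohort used by several suites
fixture_cohort6 <- function() {
  if (is.null(fixture_env$co6))
    fixture_env$co6 <- generate_cohort(cohort_spec(
      n_subjects = 6, sequences_per_subject = 3, frames_per_sequence = 30,
      seed = 7))
  fixture_env$co6
}

fixture_data6 <- function() {
  if (is.null(fixture_env$gd6))
    fixture_env$gd6 <- prepare_gait_data(fixture_cohort6())
  fixture_env$gd6
}

## very small prepared dataset for trainer mechanics (4 subjects x 2 seqs,
## 20-frame sequences)
fixture_data_tiny <- function() {
  if (is.null(fixture_env$gdt)) {
    co <- generate_cohort(cohort_spec(n_subjects = 4, sequences_per_subject = 2,
                                      frames_per_sequence = 20, seed = 13))
    fixture_env$gdt <- prepare_gait_data(co)
  }
  fixture_env$gdt
}

## fast trainer configuration used for mechanics tests (not for accuracy)
tiny_config <- function(iterations = 2L, lr = 1e-3, ...) {
  gaitscreen_config(base_channels = 2L, parts = 2L, embed_dim = 8L,
                    template = template_spec("sttg", M = 16L),
                    attention_reduction = 4L,
                    subjects_per_batch = 2L, seqs_per_subject = 2L,
                    lr = lr, iterations = iterations, seed = 5L, ...)
}

## a single synthetic dual-channel sequence with t frames
make_dual_seq <- function(t, seed = 1) {
  sil <- array(0, c(128, 128, t))
  set.seed(seed)
  for (i in seq_len(t)) {
    r0 <- sample(30:60, 1)
    sil[r0:(r0 + 40), 50:80, i] <- 1
  }
  skel <- array(round(runif(128 * 128 * t)), c(128, 128, t))
  assemble_dual_channel(sil, skel, meta = list(subject_id = "T"))
}

## ---- independent oracles -------------------------------------------------

## brute-force BA+ triplet loss: explicit triple loop over (a, p, n)
oracle_triplet <- function(emb, labels, margin) {
  if (is.matrix(emb)) dim(emb) <- c(nrow(emb), 1, ncol(emb))
  n <- dim(emb)[1]; p <- dim(emb)[2]
  per_part <- numeric(p); act_total <- 0L
  for (j in seq_len(p)) {
    hinges <- c()
    for (a in seq_len(n)) for (pp in seq_len(n)) for (nn in seq_len(n)) {
      if (pp == a || labels[pp] != labels[a] || labels[nn] == labels[a]) next
      dap <- sqrt(sum((emb[a, j, ] - emb[pp, j, ])^2))
      dan <- sqrt(sum((emb[a, j, ] - emb[nn, j, ])^2))
      hinges <- c(hinges, max(0, dap - dan + margin))
    }
    act <- hinges[hinges > 0]
    per_part[j] <- if (length(act) > 0) mean(act) else 0
    act_total <- act_total + length(act)
  }
  list(loss = mean(per_part), n_active = act_total)
}

## direct label-smoothing cross-entropy from the definition
oracle_ls_ce <- function(logits, labels, eps) {
  n <- nrow(logits); C <- ncol(logits)
  tot <- 0
  for (i in seq_len(n)) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    q <- rep(eps / (C - 1), C); q[labels[i]] <- 1 - eps
    tot <- tot - sum(q * log(p))
  }
  tot / n
}

## Mann-Whitney AUC by explicit pair comparison
oracle_auc <- function(scores, lab) {
  pos <- scores[lab == 1]; neg <- scores[lab == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## two-ECDF sweep KS
oracle_ks <- function(scores, lab) {
  xs <- sort(unique(scores))
  max(abs(vapply(xs, function(x) mean(scores[lab == 1] <= x) -
                   mean(scores[lab == 0] <= x), numeric(1))))
}

## definitional AP / INP for one probe given relevance in ranked order
oracle_ap_inp <- function(rel) {
  rk <- which(rel)
  list(ap = mean(seq_along(rk) / rk), inp = length(rk) / max(rk))
}

## construct a tie-free score set whose empirical AUC is exactly `auc`
## (n positives each beating exactly round(auc * n0) of n0 negatives)
make_auc_scores <- function(auc, n1 = 1000, n0 = 1000) {
  wins <- auc * n0
  stopifnot(abs(wins - round(wins)) < 1e-9)
  neg <- seq_len(n0)
  pos <- round(wins) + 0.1 + seq_len(n1) / (10 * n1)
  list(scores = c(pos, neg), labels = c(rep(1L, n1), rep(0L, n0)))
}

## deterministic autocorrelation-based period estimate of a series
dominant_period <- function(x, max_lag = length(x) %/% 2) {
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  which.max(ac)
}
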