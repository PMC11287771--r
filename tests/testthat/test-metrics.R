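test_that("rank-k accuracy matches an exhaustive-sort oracle", {
  ## toy task in 1-D so distances are transparent
  probe <- matrix(c(0, 10, 20), 3, 1)
  gallery <- matrix(c(1, 9, 11, 19, 30), 5, 1)
  plab <- c("a", "b", "c"); glab <- c("a", "b", "b", "x", "c")
  task <- ranking_task(probe, plab, gallery, glab)
  ## nearest neighbours: probe1 -> g1 ("a", hit); probe2 -> g2/g3 ("b", hit);
  ## probe3 -> g4 ("x", miss at k=1), rank-2 reaches no "c" (g5 at dist 10 vs
  ## g4 at 1, g3 at 9) -> exhaustive oracle
  expect_equal(as.numeric(rank_k(task, 1)), 100 * 2 / 3)
  oracle_hit <- function(k) {
    mean(vapply(1:3, function(i) {
      d <- abs(probe[i, 1] - gallery[, 1])
      any(glab[order(d)][seq_len(k)] == plab[i])
    }, logical(1)))
  }
  for (k in 1:4)
    expect_equal(as.numeric(rank_k(task, k)), 100 * oracle_hit(k))
  ## k >= gallery size with a same-label item present: always a hit
  expect_equal(as.numeric(rank_k(task, 5)), 100)
  ## gallery = probe with a single item each
  t1 <- ranking_task(matrix(1), "s", matrix(1), "s")
  expect_equal(as.numeric(rank_k(t1, 1)), 100)
})

test_that("view exclusion removes same-view gallery entries", {
  probe <- matrix(0); gallery <- matrix(c(0, 1), 2, 1)
  task <- ranking_task(probe, "s", gallery, c("s", "s"),
                       probe_view = "090", gallery_view = c("090", "054"))
  ord <- gaitscreen:::probe_order(task, 1)
  expect_identical(ord, 2L)
  ## all candidates same-view: probe excluded and counted
  t2 <- ranking_task(probe, "s", matrix(0), "s",
                     probe_view = "090", gallery_view = "090")
  r <- rank_k(t2, 1)
  expect_identical(attr(r, "excluded"), 1L)
})

test_that("mAP and mINP follow their definitional enumeration", {
  ## relevants at ranks 1 and 3 of 5: AP = (1 + 2/3)/2 = 5/6, INP = 2/3
  probe <- matrix(0)
  gallery <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  glab <- c("s", "x", "s", "x", "x")
  r <- map_minp(ranking_task(probe, "s", gallery, glab))
  expect_equal(r$map, 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(r$minp, 2 / 3, tolerance = 1e-12)
  ## single relevant at rank 1
  r1 <- map_minp(ranking_task(probe, "s", matrix(c(1, 2), 2, 1), c("s", "x")))
  expect_equal(r1$map, 100); expect_equal(r1$minp, 1)
  ## random 8x8 tasks against a brute-force oracle
  set.seed(19)
  for (rep in 1:5) {
    pe <- matrix(rnorm(8 * 3), 8, 3); ge <- matrix(rnorm(8 * 3), 8, 3)
    pl <- sample(c("a", "b"), 8, TRUE); gl <- sample(c("a", "b"), 8, TRUE)
    task <- ranking_task(pe, pl, ge, gl)
    got <- map_minp(task)
    aps <- c(); inps <- c()
    for (i in 1:8) {
      d <- sqrt(colSums((t(ge) - pe[i, ])^2))
      rel <- gl[order(d)] == pl[i]
      if (!any(rel)) next
      o <- oracle_ap_inp(rel)
      aps <- c(aps, o$ap); inps <- c(inps, o$inp)
    }
    expect_equal(got$map, 100 * mean(aps), tolerance = 1e-9)
    expect_equal(got$minp, mean(inps), tolerance = 1e-9)
  }
})

test_that("ROC AUC is the tie-corrected rank statistic", {
  ## perfect separation
  r <- roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), ci = TRUE, reps = 200)
  expect_equal(r$auc, 1)
  expect_equal(unname(r$ci), c(1, 1))
  ## all scores equal: AUC = 0.5 by the tie rule
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  ## random score sets match the Mann-Whitney pair-count oracle, with ties
  set.seed(20)
  for (rep in 1:10) {
    sc <- sample(1:8, 30, replace = TRUE)
    lab <- sample(0:1, 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(22)
  sc <- rnorm(40); lab <- rep(0:1, 20)
  a0 <- roc_auc(sc, lab)
  expect_equal(roc_auc(exp(sc), lab), a0, tolerance = 1e-12)
  expect_equal(roc_auc(3 * sc + 7, lab), a0, tolerance = 1e-12)
})

test_that("Gini = 2 AUC - 1 identically", {
  set.seed(23)
  for (rep in 1:8) {
    sc <- rnorm(30); lab <- sample(0:1, 30, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(gini_coefficient(sc, lab), 2 * roc_auc(sc, lab) - 1,
                 tolerance = 1e-12)
  }
  expect_equal(gini_coefficient(rep(1, 4), c(0, 1, 0, 1)), 0)
})

test_that("the maximum K-S statistic is the largest ECDF gap", {
  expect_equal(max_ks(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(max_ks(c(5, 7, 5, 7), c(0, 0, 1, 1)), 0)
  set.seed(24)
  for (rep in 1:8) {
    sc <- sample(1:6, 25, TRUE); lab <- sample(0:1, 25, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(max_ks(sc, lab), oracle_ks(sc, lab), tolerance = 1e-12)
  }
  ## bounded in [0, 1]
  sc <- rnorm(50); lab <- rep(0:1, 25)
  v <- max_ks(sc, lab)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("the exported ROC curve integrates back to the AUC", {
  set.seed(25)
  sc <- rnorm(30); lab <- rep(0:1, 15)
  path <- file.path(tempdir(), "roc.csv")
  curve <- export_roc(sc, lab, path)
  ## n distinct scores -> n + 1 points, from (0,0) to (1,1), sorted by
  ## threshold descending
  expect_identical(nrow(curve), length(unique(sc)) + 1L)
  expect_equal(unlist(curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(curve$threshold) < 0))
  trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(sc, lab), tolerance = 1e-9)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  summ <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(summ$auc, roc_auc(sc, lab), tolerance = 1e-9)
  ## perfect separation passes through (0, 1)
  cp <- export_roc(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_true(any(cp$fpr == 0 & cp$tpr == 1))
  unlink(c(path, paste0(path, ".json")))
})

test_that("the bootstrap CI approximately covers the true AUC", {
  ## binormal scores with true AUC 0.85; scaled-down coverage check
  true_auc <- 0.85
  delta <- sqrt(2) * qnorm(true_auc)
  cover <- 0L; reps <- 60L
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    sc <- c(rnorm(200, delta), rnorm(200))
    lab <- rep(1:0, each = 200)
    ci <- roc_auc(sc, lab, ci = TRUE, reps = 300, seed = r)$ci
    if (ci[1] <= true_auc && true_auc <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / reps, 0.9)
})
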