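test_that("the P x K sampler yields P distinct subjects with K sequences each", {
  man <- data.frame(subject_id = rep(sprintf("S%02d", 1:8), each = 6))
  smp <- pk_batch_sampler(man, P = 4, K = 6, seed = 3)
  b <- smp$next_batch()
  expect_length(b, 24)
  expect_identical(length(unique(man$subject_id[b])), 4L)
  expect_true(all(table(man$subject_id[b]) == 6))
  ## a subject with fewer than K sequences is resampled with replacement
  man2 <- data.frame(subject_id = c(rep("A", 2), rep("B", 6), rep("C", 6)))
  smp2 <- pk_batch_sampler(man2, P = 3, K = 6, seed = 4)
  b2 <- smp2$next_batch()
  expect_identical(sum(man2$subject_id[b2] == "A"), 6L)
  expect_true(all(b2[man2$subject_id[b2] == "A"] %in% 1:2))
  expect_error(pk_batch_sampler(man2, P = 4, K = 2), "subjects")
})

test_that("every subject appears at least once per epoch", {
  man <- data.frame(subject_id = rep(sprintf("S%02d", 1:12), each = 3))
  smp <- pk_batch_sampler(man, P = 5, K = 2, seed = 9)
  seen <- character(0)
  for (i in seq_len(smp$batches_per_epoch))
    seen <- union(seen, man$subject_id[smp$next_batch()])
  expect_setequal(seen, unique(man$subject_id))
})

test_that("training is deterministic at a fixed seed and logs its losses", {
  gd <- fixture_data_tiny()
  cfg <- tiny_config(iterations = 2L)
  f1 <- gaitscreen(gd, "subject", cfg)
  f2 <- gaitscreen(gd, "subject", cfg)
  ## identical L_mul at iteration 0 across fresh runs (and throughout)
  expect_identical(f1$log$l_mul, f2$log$l_mul)
  expect_named(f1$log, c("iteration", "l_tri", "l_cro", "l_mul", "active"))
  expect_true(all(is.finite(f1$log$l_mul)))
})

test_that("checkpoint resume reproduces an uninterrupted run parameter-for-parameter", {
  gd <- fixture_data_tiny()
  full <- gaitscreen(gd, "subject", tiny_config(iterations = 6L))
  half <- gaitscreen(gd, "subject", tiny_config(iterations = 3L))
  path <- file.path(tempdir(), "ck.rds")
  save_gaitscreen(half, path)
  resumed <- gaitscreen(gd, "subject", tiny_config(iterations = 6L),
                        init = load_gaitscreen(path))
  expect_equal(resumed$par, full$par, tolerance = 0)
  expect_equal(resumed$state, full$state, tolerance = 0)
  expect_identical(resumed$log$l_mul, full$log$l_mul)
  ## a configuration change is refused on resume
  other <- tiny_config(iterations = 6L, lr = 5e-3)
  expect_error(gaitscreen(gd, "subject", other, init = half), "fingerprint")
  unlink(c(path, paste0(path, ".json")))
})

test_that("evaluation embeddings are deterministic and well-shaped", {
  gd <- fixture_data_tiny()
  fit <- gaitscreen(gd, "subject", tiny_config(iterations = 2L))
  e1 <- predict(fit, gd, type = "embedding")
  e2 <- predict(fit, gd, type = "embedding")
  expect_identical(e1[, , ], e2[, , ])
  expect_identical(dim(e1), c(8L, 2L, 8L))   # n x p x d
  pr <- predict(fit, gd, type = "prob")
  expect_equal(unname(rowSums(pr[, ])), rep(1, 8), tolerance = 1e-9)
})

test_that("sequences failing the length policy are reported, not embedded", {
  gd <- fixture_data_tiny()
  fit <- gaitscreen(gd, "subject", tiny_config(iterations = 2L))
  short <- make_dual_seq(10)
  e <- suppressMessages(predict(fit, list(gd$sequences[[1]], short),
                                type = "embedding"))
  expect_identical(dim(e)[1], 1L)
  expect_identical(attr(e, "rejected"), 2L)
})

test_that("the full ablation grid builds, trains a step and embeds", {
  gd <- fixture_data_tiny()
  for (sttg in c(TRUE, FALSE)) for (dsfe in c(TRUE, FALSE)) for (mta in c(TRUE, FALSE)) {
    cfg <- tiny_config(iterations = 1L,
                       ablation = list(sttg = sttg, dsfe = dsfe, mta = mta))
    fit <- gaitscreen(gd, "subject", cfg)
    expect_true(is.finite(fit$log$l_mul[1]))
    e <- predict(fit, list(gd$sequences[[1]]), type = "embedding")
    expect_identical(dim(e), c(1L, 2L, 8L))
  }
})

test_that("the baseline wiring bypasses templates, DS-Conv2d and the MTMs", {
  cfg <- tiny_config(ablation = list(sttg = FALSE, dsfe = FALSE, mta = FALSE))
  sp <- gaitscreen:::model_specs(cfg)
  expect_null(sp$mtm)
  expect_false(any(vapply(sp$conv$layers, `[[`, logical(1), "ds")))
  expect_identical(sp$head_in, sp$c1)
  ## with sttg off the training path consumes the policy-length sequence
  s <- make_dual_seq(30)
  out <- gaitscreen:::train_sequence(s, cfg, 1, 1, 1)
  expect_identical(n_frames(out), 80L)
})

test_that("screening scores are probabilities and need a class-trained model", {
  gd <- fixture_data_tiny()
  ## attach alternating classes at the subject level
  cls <- setNames(rep(c("healthy", "impaired"), 2), unique(gd$manifest$subject_id))
  gd$manifest$class <- cls[gd$manifest$subject_id]
  fit_id <- gaitscreen(gd, "subject", tiny_config(iterations = 1L))
  expect_error(screening_score(fit_id, gd), "target = 'class'")
  fit <- gaitscreen(gd, "class", tiny_config(iterations = 2L))
  sc <- screening_score(fit, gd)
  expect_length(sc, 8)
  expect_true(all(sc >= 0 & sc <= 1))
  ## prototype scoring: higher for impaired-like sequences than its healthy
  ## reference by construction of the distance ordering
  scp <- screening_score(fit, gd, method = "prototype", ref_data = gd)
  expect_length(scp, 8)
  expect_true(all(is.finite(scp)))
})

test_that("the training loss decreases on the six-subject fixture", {
  gd <- fixture_data6()
  cfg <- gaitscreen_config(base_channels = 4L, parts = 4L, embed_dim = 32L,
                           template = template_spec("sttg", M = 16L),
                           subjects_per_batch = 2L, seqs_per_subject = 2L,
                           lr = 1e-2, iterations = 50L, seed = 6L)
  fit <- gaitscreen(gd, "subject", cfg)
  first <- mean(fit$log$l_mul[1:5])
  last <- mean(tail(fit$log$l_mul, 5))
  expect_lt(last, first)
})
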