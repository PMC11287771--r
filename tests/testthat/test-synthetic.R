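test_that("walker parameters are validated", {
  expect_error(walker_params(limb_lengths = c(torso = -1, thigh = 26, shank = 26,
                                              upper_arm = 18, forearm = 16,
                                              head_radius = 8)),
               "positive")
  expect_error(walker_params(cadence = -1), "cadence")
  expect_error(walker_params(jitter_sd = -0.1), "jitter_sd")
  w <- walker_params()
  expect_error(generate_walker(w, n_frames = 10, fps = 0), "fps")
  expect_error(generate_walker(w, n_frames = 0, fps = 25), "n_frames")
})

test_that("a zero-cadence, zero-jitter walker is a static pose", {
  w <- walker_params(cadence = 0, jitter_sd = 0, phase = 0.7)
  s <- generate_walker(w, n_frames = 6, fps = 25, seed = 3)
  for (i in 2:6) {
    expect_identical(s$silhouette[, , i], s$silhouette[, , 1])
    expect_identical(s$keypoints[, , i], s$keypoints[, , 1])
  }
})

test_that("rendering contract: binary silhouettes and 17x2 keypoints", {
  w <- walker_params(cadence = 1.7, jitter_sd = 0.05)
  s <- generate_walker(w, n_frames = 8, fps = 25, seed = 9)
  expect_true(all(s$silhouette %in% c(0L, 1L)))
  expect_identical(dim(s$silhouette), c(160L, 128L, 8L))
  expect_identical(dim(s$keypoints), c(17L, 2L, 8L))
  expect_true(all(is.finite(s$keypoints)))
})

test_that("foreground area oscillates at the step frequency", {
  ## cadence 2 steps/s at 25 fps: one step every 12.5 frames, so the
  ## autocorrelation of the pixel-count series peaks at lag 12 or 13
  w <- walker_params(cadence = 2, jitter_sd = 0)
  s <- generate_walker(w, n_frames = 100, fps = 25, seed = 1)
  area <- apply(s$silhouette, 3, sum)
  period <- dominant_period(area - mean(area), max_lag = 30)
  expect_true(period %in% 12:13)
})

test_that("cohort generation is deterministic and writes a CASIA-B-style tree", {
  spec <- cohort_spec(n_subjects = 2, sequences_per_subject = 2,
                      frames_per_sequence = 8, seed = 42)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  c1 <- generate_cohort(spec, d1)
  c2 <- generate_cohort(spec, d2)
  ## byte-identical manifests and frame images under a fixed seed
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  f1 <- list.files(d1, pattern = "png$", recursive = TRUE)
  expect_identical(f1, list.files(d2, pattern = "png$", recursive = TRUE))
  for (f in f1[c(1, 5, 9)])
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  expect_true(all(file.exists(file.path(d1, c1$manifest$path, "keypoints.json"))))
  ## refuses to clobber unless asked
  expect_error(generate_cohort(spec, d1), "overwrite")
  expect_silent(suppressMessages(generate_cohort(spec, d1, overwrite = TRUE)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("impaired subjects receive the configured speed and jitter scaling", {
  spec <- cohort_spec(n_subjects = 8, sequences_per_subject = 1,
                      frames_per_sequence = 6, seed = 21)
  co <- generate_cohort(spec)
  cls <- tapply(co$manifest$class, co$manifest$subject_id, function(z) z[1])
  expect_equal(sum(cls == "impaired"), round(8 * 0.582))
})

test_that("class label is independent of kinematics under a null effect", {
  spec <- cohort_spec(n_subjects = 8, sequences_per_subject = 1,
                      frames_per_sequence = 40, impaired_speed_ratio = 1,
                      variability_multiplier = 1, seed = 33)
  co <- generate_cohort(spec)
  ## gait frequency estimated from the silhouette-area series carries no
  ## class information when the effect dials are off
  per <- vapply(co$silhouettes, function(s) {
    area <- apply(array(as.integer(s), dim(s)), 3, sum)
    dominant_period(area - mean(area), 25)
  }, numeric(1))
  auc <- roc_auc(-per, co$manifest$class)
  expect_gt(auc, 0.2); expect_lt(auc, 0.8)
})

test_that("within-subject silhouette overlap exceeds between-subject overlap", {
  gd <- fixture_data6()
  ## per-sequence mean refined silhouette, thresholded, compared by IoU
  masks <- lapply(gd$sequences, function(s) {
    fr <- gaitscreen:::seq_frames(s)
    apply(fr[, , 1, ], c(1, 2), mean) > 0.25
  })
  iou <- function(a, b) sum(a & b) / sum(a | b)
  subj <- gd$manifest$subject_id
  wi <- c(); bw <- c()
  for (i in seq_along(masks)) for (j in seq_len(i - 1)) {
    v <- iou(masks[[i]], masks[[j]])
    if (subj[i] == subj[j]) wi <- c(wi, v) else bw <- c(bw, v)
  }
  expect_gt(mean(wi), mean(bw))
})

test_that("the screening effect size is monotone in the speed contrast", {
  ## seeded 3-point grid on (1 - impaired_speed_ratio); class separation is
  ## scored by the gait frequency estimated from the silhouette-area series,
  ## the kinematic quantity the cadence dial acts on
  aucs <- vapply(c(1, 0.9, 0.75), function(ratio) {
    co <- generate_cohort(cohort_spec(n_subjects = 10, sequences_per_subject = 1,
                                      frames_per_sequence = 50,
                                      impaired_speed_ratio = ratio,
                                      variability_multiplier = 1, seed = 55))
    freq <- vapply(co$silhouettes, function(s) {
      area <- apply(array(as.integer(s), dim(s)), 3, sum)
      1 / dominant_period(area - mean(area), 25)
    }, numeric(1))
    roc_auc(-freq, co$manifest$class)
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})
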