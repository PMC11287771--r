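## Synthetic articulated walker: a 2-D sagittal stick figure rendered as
## filled capsules (limbs) plus a head disc, with 17 pose keypoints in the
## standard COCO joint convention. Identity lives in the limb proportions;
## cognitive class acts on cadence (walking speed) and angular jitter
## (gait variability), the two gait correlates of cognitive impairment the
## screening task relies on.

#' Walker parameters
#'
#' Kinematic description of one synthetic walking subject.
#'
#' @param subject_id opaque identifier (character).
#' @param limb_lengths named numeric vector of 6 positive lengths in pixels:
#'   `torso`, `thigh`, `shank`, `upper_arm`, `forearm`, `head_radius`.
#' @param cadence steps per second (>= 0; 0 freezes the walker in a static
#'   pose). One gait cycle is two steps, so limb sinusoids run at
#'   `cadence / 2` cycles per second.
#' @param stride_amplitude peak hip flexion/extension angle, radians.
#' @param sway_amplitude torso pitch oscillation amplitude, radians.
#' @param phase gait-cycle phase offset, radians.
#' @param jitter_sd per-frame angular noise SD, radians (>= 0).
#' @param class_label `"healthy"` or `"impaired"`.
#' @return object of class `"walker_params"`.
#' @export
walker_params <- function(subject_id = "S001",
                          limb_lengths = c(torso = 40, thigh = 26, shank = 26,
                                           upper_arm = 18, forearm = 16,
                                           head_radius = 8),
                          cadence = 1.9, stride_amplitude = 0.5,
                          sway_amplitude = 0.04, phase = 0,
                          jitter_sd = 0.02,
                          class_label = c("healthy", "impaired")) {
  class_label <- match.arg(class_label)
  need <- c("torso", "thigh", "shank", "upper_arm", "forearm", "head_radius")
  if (!all(need %in% names(limb_lengths)))
    stop("limb_lengths must contain: ", paste(need, collapse = ", "))
  if (any(!is.finite(limb_lengths)) || any(limb_lengths <= 0))
    stop("all limb lengths must be positive and finite")
  stopifnot_scalar(cadence, "cadence", nonneg = TRUE)
  stopifnot_scalar(jitter_sd, "jitter_sd", nonneg = TRUE)
  stopifnot_scalar(stride_amplitude, "stride_amplitude")
  structure(list(subject_id = subject_id,
                 limb_lengths = limb_lengths[need],
                 cadence = cadence, stride_amplitude = stride_amplitude,
                 sway_amplitude = sway_amplitude, phase = phase,
                 jitter_sd = jitter_sd, class_label = class_label),
            class = "walker_params")
}

## capsule rasteriser: 0-based pixel centres, squared distance to a segment
## p1--p2 compared against (width/2)^2. Each capsule is evaluated only on
## its bounding box; parts outside the canvas are clipped.
rasterise_capsules <- function(segs, discs, H, W) {
  mask <- matrix(FALSE, H, W)
  put_capsule <- function(p1, p2, r) {
    x0 <- max(0, floor(min(p1[1], p2[1]) - r))
    x1 <- min(W - 1, ceiling(max(p1[1], p2[1]) + r))
    y0 <- max(0, floor(min(p1[2], p2[2]) - r))
    y1 <- min(H - 1, ceiling(max(p1[2], p2[2]) + r))
    if (x0 > x1 || y0 > y1) return(invisible())
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx * dx + dy * dy
    tt <- if (len2 == 0) 0
    else pmin(1, pmax(0, ((px - p1[1]) * dx + (py - p1[2]) * dy) / len2))
    hit <- (px - (p1[1] + tt * dx))^2 + (py - (p1[2] + tt * dy))^2 <= r^2
    sub <- mask[ys + 1, xs + 1, drop = FALSE]
    sub[hit] <- TRUE
    mask[ys + 1, xs + 1] <<- sub
    invisible()
  }
  for (s in segs) put_capsule(s$p1, s$p2, s$w / 2)
  for (d in discs) put_capsule(d$c, d$c, d$r)
  matrix(as.integer(mask), H, W)
}

## joint angles and positions for one frame; returns keypoints (17 x 2, COCO
## order) and the draw list. Coordinates are 0-based (x = column, y = row,
## origin top-left).
walker_pose <- function(params, tsec, jit) {
  L <- params$limb_lengths
  ph <- 2 * pi * (params$cadence / 2) * tsec + params$phase
  A <- params$stride_amplitude
  pelvis <- c(64, 92 + 1.5 * cos(2 * ph))
  th_t <- 0.06 + params$sway_amplitude * sin(2 * ph) + jit[1]
  up <- c(sin(th_t), -cos(th_t))
  neck <- pelvis + L["torso"] * up
  headc <- neck + (L["head_radius"] + 3) * up
  ## legs: right leads at phase ph, left in antiphase
  leg <- function(phl, j1, j2) {
    a <- A * sin(phl) + j1
    knee <- pelvis + L["thigh"] * c(sin(a), cos(a))
    flex <- 0.7 * max(0, sin(phl + 1.0)) + j2
    bang <- a - flex
    ankle <- knee + L["shank"] * c(sin(bang), cos(bang))
    list(knee = knee, ankle = ankle)
  }
  rl <- leg(ph, jit[2], jit[3])
  ll <- leg(ph + pi, jit[4], jit[5])
  ## arms swing in antiphase with the same-side leg
  sh <- neck - 4 * up
  arm <- function(pha, j1) {
    u <- 0.6 * A * sin(pha) + j1
    elbow <- sh + L["upper_arm"] * c(sin(u), cos(u))
    v <- u - (0.3 + 0.25 * max(0, -sin(pha)))
    wrist <- elbow + L["forearm"] * c(sin(v), cos(v))
    list(elbow = elbow, wrist = wrist)
  }
  ra <- arm(ph + pi, jit[6])
  la <- arm(ph, jit[7])
  hr <- L["head_radius"]
  kp <- rbind(
    nose = headc + c(0.6 * hr, -0.1 * hr),
    l_eye = headc + c(0.35 * hr, -0.35 * hr), r_eye = headc + c(0.25 * hr, -0.35 * hr),
    l_ear = headc + c(-0.2 * hr, -0.2 * hr), r_ear = headc + c(-0.3 * hr, -0.2 * hr),
    l_shoulder = sh + c(1.5, 0), r_shoulder = sh - c(1.5, 0),
    l_elbow = la$elbow, r_elbow = ra$elbow,
    l_wrist = la$wrist, r_wrist = ra$wrist,
    l_hip = pelvis + c(1.5, 0), r_hip = pelvis - c(1.5, 0),
    l_knee = ll$knee, r_knee = rl$knee,
    l_ankle = ll$ankle, r_ankle = rl$ankle)
  ws <- L["torso"] / 40           # widths scale with torso length
  segs <- list(
    list(p1 = pelvis, p2 = neck, w = 16 * ws),
    list(p1 = pelvis, p2 = rl$knee, w = 9 * ws),
    list(p1 = rl$knee, p2 = rl$ankle, w = 7 * ws),
    list(p1 = pelvis, p2 = ll$knee, w = 9 * ws),
    list(p1 = ll$knee, p2 = ll$ankle, w = 7 * ws),
    list(p1 = sh, p2 = ra$elbow, w = 6 * ws),
    list(p1 = ra$elbow, p2 = ra$wrist, w = 5 * ws),
    list(p1 = sh, p2 = la$elbow, w = 6 * ws),
    list(p1 = la$elbow, p2 = la$wrist, w = 5 * ws),
    list(p1 = neck, p2 = headc, w = 6 * ws))
  discs <- list(list(c = headc, r = hr))
  list(kp = kp, segs = segs, discs = discs)
}

#' Generate one synthetic gait sequence
#'
#' Renders a walking stick figure as a binary silhouette stack together with
#' the 17 COCO-convention keypoints used for rendering. Deterministic given
#' `params` and `seed`: limb angles follow sinusoids at `cadence / 2` cycles
#' per second plus seeded Gaussian angular jitter.
#'
#' @param params a [walker_params()] object.
#' @param n_frames number of frames (>= 1).
#' @param fps frames per second (> 0).
#' @param seed integer seed for the per-frame jitter stream.
#' @param canvas `c(H, W)` canvas size in pixels before silhouette
#'   refinement; default 160 x 128.
#' @return list with `silhouette` (integer array H x W x t, values 0/1) and
#'   `keypoints` (array 17 x 2 x t of 0-based (x, y) pixel coordinates).
#' @examples
#' w <- walker_params(cadence = 2, jitter_sd = 0)
#' seq <- generate_walker(w, n_frames = 10, fps = 25)
#' dim(seq$silhouette)
#' @export
generate_walker <- function(params, n_frames, fps, seed = 1L,
                            canvas = c(160L, 128L)) {
  if (!inherits(params, "walker_params")) stop("params must be a walker_params object")
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar(fps, "fps", positive = TRUE)
  H <- canvas[1]; W <- canvas[2]
  sil <- array(0L, c(H, W, n_frames))
  kp <- array(0, c(17, 2, n_frames))
  jitter <- with_seed(seed, matrix(rnorm(7 * n_frames, 0, params$jitter_sd),
                                   7, n_frames))
  for (i in seq_len(n_frames)) {
    pose <- walker_pose(params, (i - 1) / fps, jitter[, i])
    sil[, , i] <- rasterise_capsules(pose$segs, pose$discs, H, W)
    kp[, , i] <- pose$kp
  }
  list(silhouette = sil, keypoints = kp)
}

#' Cohort specification for the synthetic gait generator
#'
#' Defaults encode the screening study conditions: an impaired prevalence of
#' 0.582 and an impaired/healthy walking-speed ratio of 6.6/7.7 (healthy
#' subjects cover 4 m in 6.6 s versus 7.7 s for the impaired group), applied
#' as a multiplicative cadence reduction. `variability_multiplier` scales the
#' angular jitter SD of impaired walkers.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param sequences_per_subject sequences recorded per subject.
#' @param frames_per_sequence frames per sequence.
#' @param fps frames per second.
#' @param impaired_fraction fraction of impaired subjects in \[0, 1\].
#' @param impaired_speed_ratio cadence multiplier for impaired subjects, (0, 1].
#' @param variability_multiplier jitter-SD multiplier for impaired subjects (>= 1).
#' @param seed integer master seed; all subject and sequence substreams derive
#'   from it by counter.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 8L, sequences_per_subject = 4L,
                        frames_per_sequence = 60L, fps = 25,
                        impaired_fraction = 0.582,
                        impaired_speed_ratio = 6.6 / 7.7,
                        variability_multiplier = 2,
                        seed = 1L) {
  stopifnot_scalar(n_subjects, "n_subjects", positive = TRUE)
  stopifnot_scalar(sequences_per_subject, "sequences_per_subject", positive = TRUE)
  stopifnot_scalar(frames_per_sequence, "frames_per_sequence", positive = TRUE)
  stopifnot_scalar(fps, "fps", positive = TRUE)
  if (impaired_fraction < 0 || impaired_fraction > 1)
    stop("impaired_fraction must lie in [0, 1]")
  if (impaired_speed_ratio <= 0 || impaired_speed_ratio > 1)
    stop("impaired_speed_ratio must lie in (0, 1]")
  if (variability_multiplier < 1) stop("variability_multiplier must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 sequences_per_subject = as.integer(sequences_per_subject),
                 frames_per_sequence = as.integer(frames_per_sequence),
                 fps = fps, impaired_fraction = impaired_fraction,
                 impaired_speed_ratio = impaired_speed_ratio,
                 variability_multiplier = variability_multiplier,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic gait cohort
#'
#' Draws per-subject walker parameters (limb proportions for identity,
#' cadence/jitter for class), renders every sequence, and optionally writes a
#' CASIA-B-style tree `subject/condition/view/NNNN.png` with per-sequence
#' keypoint JSON files and a `manifest.csv`. Impaired subjects have cadence
#' scaled by `impaired_speed_ratio` and jitter SD scaled by
#' `variability_multiplier`.
#'
#' @param spec a [cohort_spec()] object.
#' @param out_dir output directory, or `NULL` (default) to keep the cohort
#'   in memory only.
#' @param overwrite allow writing into an existing non-empty `out_dir`.
#' @return object of class `"gait_cohort"`: `manifest` (data frame with
#'   subject_id, class, condition, view, path, n_frames), `silhouettes` and
#'   `keypoints` (lists, one element per sequence), and `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, overwrite = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec object")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
      stop("out_dir exists and is not empty; use overwrite = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  n <- spec$n_subjects
  n_imp <- round(n * spec$impaired_fraction)
  imp <- with_seed(derive_seed(spec$seed, "class-assignment"),
                   sample.int(n, n_imp))
  subjects <- sprintf("S%03d", seq_len(n))
  view <- "090"
  sils <- list(); kps <- list(); rows <- list()
  counter <- 0L
  for (si in seq_len(n)) {
    impaired <- si %in% imp
    sp <- with_seed(derive_seed(spec$seed, "subject", si), {
      scale <- rnorm(1, 1, 0.06)
      mult <- rnorm(6, 1, 0.04)
      ll <- c(torso = 40, thigh = 26, shank = 26, upper_arm = 18,
              forearm = 16, head_radius = 8) * scale * mult
      list(limb_lengths = ll,
           cadence = rnorm(1, 1.9, 0.095),
           stride = rnorm(1, 0.5, 0.03),
           sway = runif(1, 0.03, 0.05))
    })
    cadence <- sp$cadence * if (impaired) spec$impaired_speed_ratio else 1
    jitter <- 0.02 * if (impaired) spec$variability_multiplier else 1
    for (qi in seq_len(spec$sequences_per_subject)) {
      counter <- counter + 1L
      seq_seed <- derive_seed(spec$seed, "sequence", counter)
      phase <- with_seed(derive_seed(spec$seed, "phase", counter),
                         runif(1, 0, 2 * pi))
      wp <- walker_params(subject_id = subjects[si],
                          limb_lengths = sp$limb_lengths,
                          cadence = cadence,
                          stride_amplitude = sp$stride,
                          sway_amplitude = sp$sway, phase = phase,
                          jitter_sd = jitter,
                          class_label = if (impaired) "impaired" else "healthy")
      gw <- generate_walker(wp, spec$frames_per_sequence, spec$fps,
                            seed = seq_seed)
      cond <- sprintf("nm-%02d", qi)
      rel <- file.path(subjects[si], cond, view)
      ## silhouettes kept as raw bytes (values 0/1) to bound cohort memory
      sils[[counter]] <- array(as.raw(gw$silhouette), dim(gw$silhouette))
      kps[[counter]] <- gw$keypoints
      rows[[counter]] <- data.frame(
        subject_id = subjects[si],
        class = if (impaired) "impaired" else "healthy",
        condition = cond, view = view, path = rel,
        n_frames = spec$frames_per_sequence, stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        dd <- file.path(out_dir, rel)
        dir.create(dd, showWarnings = FALSE, recursive = TRUE)
        for (fi in seq_len(spec$frames_per_sequence))
          png::writePNG(gw$silhouette[, , fi] * 1.0,
                        file.path(dd, sprintf("%04d.png", fi - 1L)))
        jsonlite::write_json(
          list(frames = lapply(seq_len(spec$frames_per_sequence),
                               function(fi) unname(gw$keypoints[, , fi]))),
          file.path(dd, "keypoints.json"), digits = NA, auto_unbox = TRUE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, silhouettes = sils, keypoints = kps,
                 spec = spec),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("Synthetic gait cohort: %d subjects x %d sequences (%d impaired subjects)\n",
              x$spec$n_subjects, x$spec$sequences_per_subject,
              sum(tapply(x$manifest$class, x$manifest$subject_id,
                         function(z) z[1]) == "impaired")))
  invisible(x)
}
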