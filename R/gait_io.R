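## Reading, refining and assembling gait sequences.
##
## Coordinate conventions: 0-based, origin top-left, x = column, y = row.
## The refinement contract: largest connected foreground component, minimal
## bounding rectangle, nearest-neighbour scale to height 256 (aspect
## preserved), horizontally centred paste onto a 256 x 256 canvas, exact
## 2 x 2 block-average down to 128 x 128. With these resampling choices the
## operation is an exact fixed point on its own output.

#' Refine a raw silhouette mask
#'
#' Selects the largest connected foreground component, crops its bounding
#' rectangle, scales it to height 256 preserving aspect ratio, pastes it
#' horizontally centred on a 256 x 256 canvas and reduces the canvas to
#' 128 x 128 by 2 x 2 block averaging.
#'
#' @param raw_mask numeric/integer/logical matrix; foreground is `> 0`.
#' @param keypoints optional 17 x 2 matrix of 0-based (x, y) coordinates in
#'   `raw_mask` space; if given they are mapped through the same transform.
#' @return 128 x 128 matrix with values in \[0, 1\]. If `keypoints` were
#'   supplied, a list with elements `image`, `keypoints` (mapped to the
#'   128 x 128 frame) and `transform` (`list(a, bx, by)` with
#'   `x128 = a * x + bx`, `y128 = a * y + by`).
#' @export
refine_silhouette <- function(raw_mask, keypoints = NULL) {
  m <- (as.matrix(raw_mask) > 0) * 1L
  if (!any(m == 1L)) {
    cond <- simpleError("empty silhouette: no foreground pixel")
    class(cond) <- c("empty_silhouette", class(cond))
    stop(cond)
  }
  lab <- EBImage::bwlabel(m)
  areas <- tabulate(lab[lab > 0])
  comp <- (lab == which.max(areas)) * 1L
  rr <- range(which(rowSums(comp) > 0)); cc <- range(which(colSums(comp) > 0))
  ## keep the component's original (possibly fractional) values: this is
  ## what makes re-refining an already-refined silhouette a no-op
  vals <- as.matrix(raw_mask) * comp
  crop <- vals[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  h <- nrow(crop); w <- ncol(crop)
  sf <- 256 / h
  ws <- max(1L, as.integer(round(w * sf)))
  ## nearest-neighbour resample, centre-aligned grids
  src_r <- pmin(h, pmax(1L, floor((seq_len(256) - 0.5) / sf) + 1L))
  src_c <- pmin(w, pmax(1L, floor((seq_len(ws) - 0.5) * w / ws) + 1L))
  scaled <- crop[src_r, src_c, drop = FALSE]
  canvas <- matrix(0L, 256, 256)
  ## centre with the left edge on an even column: parity-stable under the
  ## 2x2 block average, which is what makes refinement a fixed point
  q <- (256L - ws) %/% 2L
  left <- q - q %% 2L + 1L         # 1-based paste column, even 0-based edge
  keep <- seq_len(ws) + left - 1L
  inside <- keep >= 1L & keep <= 256L
  canvas[, keep[inside]] <- scaled[, inside, drop = FALSE]
  ## exact 2x2 block average
  half <- (canvas[seq(1, 255, 2), ] + canvas[seq(2, 256, 2), ])
  out <- (half[, seq(1, 255, 2)] + half[, seq(2, 256, 2)]) / 4
  if (is.null(keypoints)) return(out)
  a <- sf / 2
  bx <- (sf * (0.5 - (cc[1] - 1)) + (left - 1)) / 2 - 0.5
  by <- (sf * (0.5 - (rr[1] - 1)) - 0.5) / 2 - 0.25
  kp <- cbind(a * keypoints[, 1] + bx, a * keypoints[, 2] + by)
  list(image = out, keypoints = kp, transform = list(a = a, bx = bx, by = by))
}

## fixed 16-edge connectivity over the 17 COCO keypoints:
## nose-eyes, eyes-ears, shoulder bar, arms, torso sides, hip bar, legs
skeleton_edges <- function() {
  rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 5),
        c(6, 7), c(6, 8), c(8, 10), c(7, 9), c(9, 11),
        c(6, 12), c(7, 13), c(12, 13),
        c(12, 14), c(14, 16), c(13, 15), c(15, 17))
}

#' Render a skeleton map from keypoints
#'
#' Draws the 17 joints as discs (radius 2 px) and 16 limb segments as 2-px
#' wide lines on a `size` x `size` canvas. Keypoints are expected in the
#' coordinate frame produced by [refine_silhouette()]. Points outside the
#' canvas are clipped with a warning.
#'
#' @param keypoints 17 x 2 matrix of 0-based (x, y) coordinates.
#' @param size canvas side length in pixels (default 128).
#' @return `size` x `size` matrix with values in \[0, 1\].
#' @export
render_skeleton_map <- function(keypoints, size = 128L) {
  if (!is.matrix(keypoints) || nrow(keypoints) != 17 || ncol(keypoints) != 2)
    stop("keypoints must be a 17 x 2 matrix")
  if (any(keypoints < -0.5 | keypoints > size - 0.5))
    warning("keypoints outside canvas; drawing is clipped")
  edges <- skeleton_edges()
  segs <- lapply(seq_len(nrow(edges)), function(i)
    list(p1 = keypoints[edges[i, 1], ], p2 = keypoints[edges[i, 2], ], w = 2))
  discs <- lapply(seq_len(17), function(i) list(c = keypoints[i, ], r = 2))
  rasterise_capsules(segs, discs, size, size) * 1
}

## ---- sequence containers -------------------------------------------------

#' Assemble a dual-channel sequence
#'
#' Stacks refined silhouette frames (channel 1) and rendered skeleton maps
#' (channel 2) into the network input: t frames x 2 channels x 128 x 128.
#' Binary-valued stacks are stored as raw bytes internally; frames are
#' materialised to double precision on demand.
#'
#' @param sil 128 x 128 x t array of silhouette frames, values in \[0, 1\].
#' @param skel 128 x 128 x t array of skeleton maps, or `NULL` for a zero
#'   skeleton channel (silhouette-only sequences).
#' @param meta named list of sequence metadata (subject, class, condition, view).
#' @return object of class `"dual_channel_sequence"`.
#' @export
assemble_dual_channel <- function(sil, skel = NULL, meta = list()) {
  ds <- dim(sil)
  if (length(ds) != 3 || ds[1] != 128 || ds[2] != 128)
    stop("sil must be a 128 x 128 x t array")
  if (is.null(skel)) skel <- array(0, ds)
  if (!identical(dim(skel)[3], ds[3]) || any(dim(skel)[1:2] != 128))
    stop("silhouette and skeleton stacks must have equal length t and size 128")
  tensor <- array(0, c(128, 128, 2, ds[3]))
  tensor[, , 1, ] <- as.numeric(sil)
  tensor[, , 2, ] <- as.numeric(skel)
  ## quarter-integer values (binary masks and block-averaged silhouettes)
  ## are stored losslessly as raw bytes at scale 4 to bound memory
  t4 <- tensor * 4
  exact <- max(tensor) <= 1 && min(tensor) >= 0 && !any(t4 != round(t4))
  data <- if (exact) array(as.raw(t4), dim(tensor)) else tensor
  structure(list(data = data, frame_idx = seq_len(ds[3]), meta = meta),
            class = "dual_channel_sequence")
}

#' Number of frames of a sequence
#' @param x a sequence object.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.dual_channel_sequence <- function(x) length(x$frame_idx)

#' @export
n_frames.default <- function(x) dim(x)[length(dim(x))]

## materialise (a subset of) frames as a double array 128 x 128 x 2 x T
seq_frames <- function(x, idx = NULL) {
  idx <- idx %||% x$frame_idx
  d <- x$data
  if (is.raw(d)) {
    out <- array(as.integer(d[, , , idx, drop = FALSE]) / 4,
                 c(128, 128, 2, length(idx)))
  } else {
    out <- d[, , , idx, drop = FALSE]
  }
  out
}

reindex_seq <- function(x, idx) { x$frame_idx <- idx; x }

#' @export
print.dual_channel_sequence <- function(x, ...) {
  cat(sprintf("dual-channel gait sequence: %d frames, 2 x 128 x 128 (%s)\n",
              n_frames(x), if (is.raw(x$data)) "binary/raw" else "double"))
  invisible(x)
}

#' Write / read a dual-channel sequence
#'
#' Frames are stored as paired PNGs (`sil_NNNN.png`, `skel_NNNN.png`) plus a
#' `meta.json`. Binary stacks round-trip bitwise exactly.
#'
#' @param x a `dual_channel_sequence`.
#' @param dir output directory (created if needed).
#' @return `write_dual_channel` returns `dir` invisibly; `read_dual_channel`
#'   returns the sequence.
#' @export
write_dual_channel <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- seq_frames(x)
  for (i in seq_len(dim(fr)[4])) {
    png::writePNG(fr[, , 1, i], file.path(dir, sprintf("sil_%04d.png", i - 1L)))
    png::writePNG(fr[, , 2, i], file.path(dir, sprintf("skel_%04d.png", i - 1L)))
  }
  jsonlite::write_json(x$meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dual_channel
#' @export
read_dual_channel <- function(dir) {
  sf <- sort(list.files(dir, pattern = "^sil_.*\\.png$", full.names = TRUE),
             method = "radix")
  kf <- sort(list.files(dir, pattern = "^skel_.*\\.png$", full.names = TRUE),
             method = "radix")
  tlen <- length(sf)
  sil <- array(0, c(128, 128, tlen)); skel <- array(0, c(128, 128, tlen))
  for (i in seq_len(tlen)) {
    sil[, , i] <- png::readPNG(sf[i])
    skel[, , i] <- png::readPNG(kf[i])
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  assemble_dual_channel(sil, skel, meta)
}

## ---- sequence-length policy ---------------------------------------------

#' Apply the training sequence-length policy
#'
#' Sequences shorter than `min_len` frames are discarded; sequences between
#' `min_len` and `target_len` frames are cyclically repeated up to exactly
#' `target_len`; longer sequences are randomly cropped to `target_len`
#' contiguous frames in training mode and passed through unchanged in
#' evaluation mode.
#'
#' @param seq a `dual_channel_sequence`.
#' @param min_len minimum admissible length (default 15).
#' @param target_len analysis length (default 80).
#' @param mode `"train"` or `"eval"`.
#' @param seed optional seed for the training-mode crop.
#' @return the adjusted sequence, or an object of class
#'   `"rejected_sequence"` (see [is_rejected()]) carrying the reason.
#' @export
apply_length_policy <- function(seq, min_len = 15L, target_len = 80L,
                                mode = c("train", "eval"), seed = NULL) {
  mode <- match.arg(mode)
  t <- n_frames(seq)
  if (t < min_len) {
    message(sprintf("sequence rejected: %d frames < minimum %d", t, min_len))
    return(structure(list(reason = sprintf("too short (%d < %d)", t, min_len)),
                     class = "rejected_sequence"))
  }
  if (t < target_len)
    return(reindex_seq(seq, rep(seq$frame_idx, length.out = target_len)))
  if (t == target_len || mode == "eval") return(seq)
  start <- if (is.null(seed)) sample.int(t - target_len + 1L, 1L)
  else with_seed(seed, sample.int(t - target_len + 1L, 1L))
  reindex_seq(seq, seq$frame_idx[start:(start + target_len - 1L)])
}

#' Test whether a sequence was rejected by the length policy
#' @param x object returned by [apply_length_policy()].
#' @export
is_rejected <- function(x) inherits(x, "rejected_sequence")

## ---- dataset loading ------------------------------------------------------

#' Load a gait dataset from disk
#'
#' Walks a CASIA-B-style tree `subject/condition/view/NNNN.png` (one PNG per
#' frame, plus an optional `keypoints.json` per sequence directory) and builds
#' a manifest sorted lexicographically. Sequences are loaded lazily through
#' the returned accessor.
#'
#' @param root dataset root directory.
#' @return object of class `"gait_dataset"`: `manifest` data frame,
#'   `root`, and `load_sequence(i)` returning
#'   `list(silhouette = HxWxt array, keypoints = 17x2xt array or NULL)`.
#' @export
load_gait_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  dirs <- list.dirs(root, recursive = TRUE, full.names = FALSE)
  dirs <- dirs[vapply(strsplit(dirs, "/"), length, 1L) == 3L]
  dirs <- sort(dirs, method = "radix")
  if (length(dirs) == 0) stop("no subject/condition/view directories under ", root)
  rows <- lapply(dirs, function(d) {
    parts <- strsplit(d, "/")[[1]]
    pngs <- list.files(file.path(root, d), pattern = "\\.png$")
    if (length(pngs) == 0) return(NULL)
    data.frame(subject_id = parts[1], condition = parts[2], view = parts[3],
               path = d, n_frames = length(pngs),
               has_keypoints = file.exists(file.path(root, d, "keypoints.json")),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest)) stop("no PNG frames found under ", root)
  mf <- file.path(root, "manifest.csv")
  if (file.exists(mf)) {
    extra <- read.csv(mf, stringsAsFactors = FALSE)
    if ("class" %in% names(extra))
      manifest$class <- extra$class[match(manifest$path, extra$path)]
  }
  load_sequence <- function(i) {
    d <- file.path(root, manifest$path[i])
    pngs <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE),
                 method = "radix")
    fr1 <- png::readPNG(pngs[1])
    sil <- array(0, c(nrow(fr1), ncol(fr1), length(pngs)))
    sil[, , 1] <- fr1
    for (j in seq_along(pngs)[-1]) sil[, , j] <- png::readPNG(pngs[j])
    kp <- NULL
    kf <- file.path(d, "keypoints.json")
    if (file.exists(kf)) {
      fr <- jsonlite::read_json(kf, simplifyVector = TRUE)$frames
      if (is.list(fr)) fr <- simplify2array(fr) else fr <- aperm(fr, c(2, 3, 1))
      kp <- fr
    } else {
      warning("missing keypoints for ", manifest$path[i],
              "; sequence is silhouette-only")
    }
    list(silhouette = sil, keypoints = kp)
  }
  structure(list(manifest = manifest, root = root,
                 load_sequence = load_sequence),
            class = "gait_dataset")
}

## ---- preparation: raw sequences -> network-ready dual-channel stacks -----

#' Prepare network-ready gait data
#'
#' Refines every silhouette frame, maps and renders the paired keypoints
#' through the same transform, and assembles dual-channel 128 x 128 stacks.
#' Frames with an empty silhouette are dropped (with a message).
#'
#' @param x a `gait_cohort` (in-memory) or `gait_dataset` (on-disk) object.
#' @return object of class `"gait_data"`: `manifest` plus `sequences`, a list
#'   of `dual_channel_sequence` objects.
#' @export
prepare_gait_data <- function(x) UseMethod("prepare_gait_data")

prepare_one <- function(sil, kp, meta) {
  tlen <- dim(sil)[3]
  rs <- array(0, c(128, 128, tlen)); rk <- array(0, c(128, 128, tlen))
  keep <- logical(tlen)
  for (i in seq_len(tlen)) {
    m <- sil[, , i]
    if (is.raw(m)) m <- matrix(as.integer(m), nrow(sil), ncol(sil))
    res <- tryCatch(refine_silhouette(m, keypoints = if (is.null(kp)) NULL else kp[, , i]),
                    empty_silhouette = function(e) NULL)
    if (is.null(res)) next
    keep[i] <- TRUE
    if (is.null(kp)) {
      rs[, , i] <- res
    } else {
      rs[, , i] <- res$image
      rk[, , i] <- render_skeleton_map(res$keypoints)
    }
  }
  if (!all(keep)) {
    message(sprintf("dropped %d empty frame(s) in %s",
                    sum(!keep), meta$subject_id %||% "?"))
    rs <- rs[, , keep, drop = FALSE]; rk <- rk[, , keep, drop = FALSE]
  }
  ## refined silhouettes are quarter-integer valued; snap binaries to raw
  ## storage only when exactly binary, otherwise keep double precision
  assemble_dual_channel(rs, if (is.null(kp)) NULL else rk, meta)
}

#' @export
prepare_gait_data.gait_cohort <- function(x) {
  seqs <- vector("list", nrow(x$manifest))
  for (i in seq_len(nrow(x$manifest))) {
    meta <- as.list(x$manifest[i, c("subject_id", "class", "condition", "view")])
    seqs[[i]] <- prepare_one(x$silhouettes[[i]], x$keypoints[[i]], meta)
  }
  structure(list(manifest = x$manifest, sequences = seqs), class = "gait_data")
}

#' @export
prepare_gait_data.gait_dataset <- function(x) {
  seqs <- vector("list", nrow(x$manifest))
  for (i in seq_len(nrow(x$manifest))) {
    raw <- x$load_sequence(i)
    meta <- as.list(x$manifest[i, intersect(c("subject_id", "class", "condition", "view"),
                                            names(x$manifest))])
    seqs[[i]] <- prepare_one(raw$silhouette, raw$keypoints, meta)
  }
  structure(list(manifest = x$manifest, sequences = seqs), class = "gait_data")
}

#' @export
print.gait_data <- function(x, ...) {
  cat(sprintf("gait_data: %d sequences, %d subjects\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id))))
  invisible(x)
}
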