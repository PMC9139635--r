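# Synthetic speckle phantom generator.
#
# Emulates the phenomenology of B-mode breast ultrasound at desk scale:
# multiplicative gamma speckle on a homogeneous background, a hypoechoic
# star-convex lesion whose boundary irregularity (spiculation) and
# eccentricity encode the class (benign lesions are near-circular and round,
# malignant ones spiculated and elongated), plus the three quality-degrading
# artifacts the score-pooling mechanism exists for: acoustic shadow, motion
# blur, and gain error. No acoustic realism beyond this is claimed.

#' Phantom generator configuration
#'
#' The defaults are calibrated so that clean frames land mid-range on both
#' default quality gates (brightness 10-30, blurriness 200-300): the
#' background level sets the brightness score, and the speckle contrast
#' (gamma shape; lower = spikier) sets the variance-of-Laplacian scale.
#'
#' @param frame_size Square frame edge in pixels (default 64; 224 supported).
#' @param background_mean Mean background intensity (default 25).
#' @param speckle_shape Gamma shape of the sparse multiplicative speckle
#'   component (default 0.10; lower = spikier). Together with
#'   `background_mean` this sets where clean frames land on the brightness
#'   and blurriness gates.
#' @param speckle_correlation Gaussian sigma (pixels) of the spatial
#'   correlation applied to the sparse component (default 0.6), emulating
#'   the finite resolution cell.
#' @param speckle_cv Optional amplitude of an additive band-limited
#'   speckle component (default 0 = off): white noise shaped by an
#'   iterated Laplacian-of-Gaussian band-pass at the resolution-cell
#'   frequency, which raises the blurriness score at a given overall
#'   contrast.
#' @param speckle_cell_sigma Gaussian sigma (pixels) defining the
#'   band-limited component's cell size (default 1, about a 6 px cell).
#' @param lesion_radius_range Lesion radius as a fraction of the frame edge
#'   (default 0.1-0.3).
#' @param lesion_contrast Intensity shift of the hypoechoic lesion relative
#'   to the background (default -20; the lesion level is floored at 2).
#' @param spiculation_amplitude Named pair of boundary-irregularity
#'   amplitudes, `benign` (default 0.05) and `malignant` (default 0.4),
#'   as fractions of the lesion radius.
#' @param n_spicules Spicule count for the sinusoidal boundary modulation
#'   (default 8).
#' @param axis_ratio_range Named list of minor/major axis-ratio ranges:
#'   benign lesions are round (default 0.85-1), malignant ones elongated
#'   (default 0.5-0.75).
#' @param shadow_prob,blur_prob,gain_prob Per-frame artifact probabilities
#'   (defaults 0; corruption in [generate_sequence()] is driven by
#'   `corrupt_fraction` instead).
#' @param blur_sigma Gaussian sigma of the motion-blur artifact (default 3).
#' @param gain_range Multiplicative gain factor range for the gain artifact
#'   (default 0.3-2.5).
#' @param seed Optional seed recorded with the config (generators use the
#'   caller's RNG stream; see [generate_dataset()]).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(frame_size = 64L, background_mean = 25,
                           speckle_shape = 0.10, speckle_correlation = 0.6,
                           speckle_cv = 0, speckle_cell_sigma = 1,
                           lesion_radius_range = c(0.1, 0.3),
                           lesion_contrast = -20,
                           spiculation_amplitude = c(benign = 0.05, malignant = 0.4),
                           n_spicules = 8L,
                           axis_ratio_range = list(
                             benign = c(0.85, 1), malignant = c(0.5, 0.75)
                           ),
                           shadow_prob = 0, blur_prob = 0, gain_prob = 0,
                           blur_sigma = 3, gain_range = c(0.3, 2.5),
                           seed = NULL) {
  stopifnot(
    frame_size >= 16L, background_mean > 0, background_mean <= 255,
    speckle_shape > 0, speckle_correlation >= 0,
    speckle_cv >= 0, speckle_cell_sigma > 0,
    length(lesion_radius_range) == 2L,
    all(lesion_radius_range > 0), all(lesion_radius_range < 0.5),
    all(c("benign", "malignant") %in% names(spiculation_amplitude)),
    n_spicules >= 1L,
    shadow_prob >= 0, shadow_prob <= 1, blur_prob >= 0, blur_prob <= 1,
    gain_prob >= 0, gain_prob <= 1, blur_sigma > 0,
    length(gain_range) == 2L, all(gain_range > 0)
  )
  structure(
    list(
      frame_size = as.integer(frame_size), background_mean = background_mean,
      speckle_shape = speckle_shape, speckle_correlation = speckle_correlation,
      speckle_cv = speckle_cv, speckle_cell_sigma = speckle_cell_sigma,
      lesion_radius_range = lesion_radius_range,
      lesion_contrast = lesion_contrast,
      spiculation_amplitude = spiculation_amplitude,
      n_spicules = as.integer(n_spicules),
      axis_ratio_range = axis_ratio_range,
      shadow_prob = shadow_prob, blur_prob = blur_prob, gain_prob = gain_prob,
      blur_sigma = blur_sigma, gain_range = gain_range, seed = seed
    ),
    class = "phantom_config"
  )
}

# Two-component speckle, unit mean, floored at a small positive value:
# (1) a sparse gamma component (spiky bright scatterers, lightly spatially
# correlated), plus (2) a zero-mean band-limited component - white noise
# shaped by three passes of the Laplacian-of-Gaussian band-pass, which
# concentrates its energy at the resolution-cell frequency and therefore
# carries most of the Laplacian-variance (blurriness) mass of a clean
# frame at moderate amplitude.
speckle_field <- function(n, m, config) {
  s <- matrix(rgamma(n * m, config$speckle_shape, config$speckle_shape), n, m)
  if (config$speckle_correlation > 0) {
    s <- gaussian_smooth(s, config$speckle_correlation)
  }
  if (config$speckle_cv > 0) {
    b <- matrix(rnorm(n * m), n, m)
    for (i in 1:3) b <- laplacian_filter(gaussian_smooth(b, config$speckle_cell_sigma))
    s <- s + config$speckle_cv * b / stats::sd(b)
  }
  pmax(s, 0.02)
}

# Draw lesion geometry for a sequence (shared across its frames).
draw_lesion_geometry <- function(config, label) {
  n <- config$frame_size
  r_frac <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
  arr <- config$axis_ratio_range[[label]]
  list(
    cx = runif(1, 0.35, 0.65) * n,
    cy = runif(1, 0.35, 0.65) * n,
    radius = r_frac * n,
    amplitude = unname(config$spiculation_amplitude[[label]]),
    n_spicules = config$n_spicules,
    phase = runif(1, 0, 2 * pi),
    axis_ratio = runif(1, arr[1], arr[2]),
    orientation = runif(1, 0, pi)
  )
}

lesion_mask <- function(geom, n, dx = 0, dy = 0) {
  xs <- matrix(rep(seq_len(n), times = n), n, n) - (geom$cy + dy) # rows
  ys <- matrix(rep(seq_len(n), each = n), n, n) - (geom$cx + dx) # cols
  co <- cos(geom$orientation); si <- sin(geom$orientation)
  u <- co * xs + si * ys
  v <- (-si * xs + co * ys) / geom$axis_ratio
  rr <- sqrt(u^2 + v^2)
  ang <- atan2(v, u)
  boundary <- geom$radius *
    (1 + geom$amplitude * sin(geom$n_spicules * ang + geom$phase))
  rr <= boundary
}

apply_shadow <- function(frame, strength = 0.5) {
  n <- nrow(frame); m <- ncol(frame)
  w <- sample(seq(floor(0.3 * m), floor(0.6 * m)), 1)
  c0 <- sample(seq_len(m - w + 1), 1)
  r0 <- sample(seq(floor(0.2 * n), floor(0.6 * n)), 1)
  frame[r0:n, c0:(c0 + w - 1)] <- frame[r0:n, c0:(c0 + w - 1)] * strength
  frame
}

finalize_frame <- function(frame) {
  round(pmin(pmax(frame, 0), 255))
}

#' Generate one phantom frame
#'
#' Builds a speckled background, inserts the hypoechoic lesion, optionally
#' applies the configured artifacts (shadow, blur, gain) with their
#' probabilities, clips to \[0, 255\] and rounds to integer intensities.
#' Consumes the caller's RNG stream; seed it for reproducibility.
#'
#' @param config A [phantom_config()].
#' @param label `"benign"` or `"malignant"` (controls lesion morphology).
#' @param geometry Optional lesion geometry (from a sequence) to reuse;
#'   drawn fresh when NULL.
#' @param jitter Length-2 numeric lesion center offset in pixels.
#' @return A list with `pixels` (integer-valued matrix in \[0, 255\]) and
#'   `mask` (logical lesion mask).
#' @export
generate_frame <- function(config, label, geometry = NULL, jitter = c(0, 0)) {
  stopifnot(inherits(config, "phantom_config"))
  label <- normalize_label(label)
  n <- config$frame_size
  if (is.null(geometry)) geometry <- draw_lesion_geometry(config, label)
  frame <- config$background_mean * speckle_field(n, n, config)
  mask <- lesion_mask(geometry, n, jitter[1], jitter[2])
  level <- max(config$background_mean + config$lesion_contrast, 2)
  frame[mask] <- level * speckle_field(n, n, config)[mask]
  if (runif(1) < config$shadow_prob) frame <- apply_shadow(frame)
  if (runif(1) < config$blur_prob) {
    frame <- gaussian_smooth(frame, config$blur_sigma)
  }
  if (runif(1) < config$gain_prob) {
    frame <- frame * runif(1, config$gain_range[1], config$gain_range[2])
  }
  list(pixels = finalize_frame(frame), mask = mask)
}

# Degrade a clean frame so that it violates at least one default quality
# gate; escalates until the violation holds.
corrupt_frame <- function(frame, config, thresholds, sigma = 1) {
  kind <- sample(c("blur", "shadow", "gain"), 1)
  out <- frame
  if (kind == "blur") {
    out <- finalize_frame(gaussian_smooth(frame, config$blur_sigma))
  } else if (kind == "gain") {
    # draw from the tails of the gain range so the brightness gate trips
    g <- if (runif(1) < 0.5) {
      runif(1, config$gain_range[1], 0.34)
    } else {
      runif(1, 1.8, config$gain_range[2])
    }
    out <- finalize_frame(frame * g)
  } else {
    out <- finalize_frame(apply_shadow(frame, strength = 0.25))
  }
  q <- assess_frame(out, thresholds, sigma)
  tries <- 0L
  while (q$gate == 1L && tries < 8L) {
    # escalate: blur harder, then dim
    out <- finalize_frame(gaussian_smooth(out, config$blur_sigma))
    if (tries >= 2L) out <- finalize_frame(out * 0.35)
    q <- assess_frame(out, thresholds, sigma)
    tries <- tries + 1L
  }
  list(pixels = out, kind = kind)
}

#' Generate a phantom BUS sequence
#'
#' Draws one lesion geometry, then renders `n_frames` frames of it with
#' fresh speckle and a small random translation (at most 2 px) per frame. A
#' `corrupt_fraction` of the frames (rounded) receive a degradation (blur,
#' shadow, or gain) that is verified to violate a default quality gate;
#' clean frames that accidentally fail the gates due to speckle variance
#' are resampled a few times.
#'
#' @param config A [phantom_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param n_frames Number of frames (default 15).
#' @param corrupt_fraction Fraction of frames to degrade (default 0).
#' @param sequence_id Identifier for the sequence.
#' @param thresholds Gates used for the corruption/cleanliness checks
#'   (default [quality_thresholds()]).
#' @return A list with `sequence` (a [bus_sequence()]), `corrupted`
#'   (logical per-frame flags) and `masks` (per-frame lesion masks).
#' @export
generate_sequence <- function(config, label, n_frames = 15L,
                              corrupt_fraction = 0,
                              sequence_id = "phantom",
                              thresholds = quality_thresholds()) {
  stopifnot(n_frames >= 1L, corrupt_fraction >= 0, corrupt_fraction <= 1)
  label <- normalize_label(label)
  geometry <- draw_lesion_geometry(config, label)
  n_corrupt <- round(n_frames * corrupt_fraction)
  corrupt_idx <- if (n_corrupt > 0) sample.int(n_frames, n_corrupt) else integer(0)
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  corrupted <- logical(n_frames)
  for (i in seq_len(n_frames)) {
    jitter <- runif(2, -2, 2)
    f <- generate_frame(config, label, geometry, jitter)
    if (i %in% corrupt_idx) {
      cf <- corrupt_frame(f$pixels, config, thresholds)
      frames[[i]] <- cf$pixels
      corrupted[i] <- TRUE
    } else {
      # resample frames that fail the gates by speckle accident
      tries <- 0L
      while (assess_frame(f$pixels, thresholds)$gate == 0L && tries < 5L) {
        f <- generate_frame(config, label, geometry, jitter)
        tries <- tries + 1L
      }
      frames[[i]] <- f$pixels
    }
    masks[[i]] <- f$mask
  }
  list(
    sequence = bus_sequence(frames, sequence_id = sequence_id, label = label),
    corrupted = corrupted,
    masks = masks
  )
}

# Deterministic 70/15/15 split of n sequence indices (at least one element
# in train; val/test get their rounded shares).
split_indices <- function(n) {
  n_val <- max(if (n >= 7) 1L else 0L, round(0.15 * n))
  n_test <- max(if (n >= 7) 1L else 0L, round(0.15 * n))
  n_train <- n - n_val - n_test
  rep(c("train", "val", "test"), c(n_train, n_val, n_test))
}

#' Generate an in-memory phantom study
#'
#' Produces labelled phantom sequences for both classes with a deterministic
#' sequence-level 70/15/15 train/val/test split. Used by the end-to-end
#' experiments and tests; see [generate_dataset()] for the on-disk variant.
#'
#' @param n_benign,n_malignant Sequence counts per class.
#' @param frames_per_sequence Frames per sequence (default 15).
#' @param corrupt_fraction Fraction of degraded frames per sequence
#'   (default 0).
#' @param config A [phantom_config()].
#' @param seed RNG seed for the whole study.
#' @return Tibble with one row per sequence: `sequence` (list column of
#'   [bus_sequence()]), `label`, `split`, `corrupted` and `masks` list
#'   columns.
#' @export
generate_phantom_study <- function(n_benign, n_malignant,
                                   frames_per_sequence = 15L,
                                   corrupt_fraction = 0,
                                   config = phantom_config(), seed = 1L) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  counts <- c(benign = n_benign, malignant = n_malignant)
  for (label in c("benign", "malignant")) {
    n <- counts[[label]]
    splits <- sample(split_indices(n))
    for (i in seq_len(n)) {
      id <- sprintf("%s%03d", substr(label, 1, 3), i)
      g <- generate_sequence(config, label, frames_per_sequence,
        corrupt_fraction,
        sequence_id = id
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sequence_id = id, label = label, split = splits[i],
        sequence = list(g$sequence), corrupted = list(g$corrupted),
        masks = list(g$masks)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a phantom dataset to disk
#'
#' Generates sequences for both classes, writes each as a directory of
#' 8-bit grayscale PNG frames, and writes a `manifest.csv` with the
#' deterministic 70/15/15 sequence-level split. Byte-reproducible for a
#' fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_benign,n_malignant Sequence counts per class.
#' @param frames_per_sequence Frames per sequence (default 20).
#' @param corrupt_fraction Fraction of degraded frames per sequence
#'   (default 0).
#' @param config A [phantom_config()].
#' @param seed RNG seed.
#' @return Path of the manifest CSV, invisibly.
#' @export
generate_dataset <- function(out_dir, n_benign, n_malignant,
                             frames_per_sequence = 20L,
                             corrupt_fraction = 0,
                             config = phantom_config(), seed = 1L) {
  study <- generate_phantom_study(
    n_benign, n_malignant, frames_per_sequence,
    corrupt_fraction, config, seed
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(study))) {
    seq_dir <- file.path(out_dir, study$sequence_id[i])
    dir.create(seq_dir, showWarnings = FALSE)
    frames <- study$sequence[[i]]$frames
    for (j in seq_along(frames)) {
      write_frame_png(frames[[j]], file.path(seq_dir, sprintf("frame%03d.png", j - 1L)))
    }
  }
  manifest <- data.frame(
    sequence_directory = study$sequence_id,
    label = study$label,
    split = study$split
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
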