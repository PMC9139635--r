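# Per-frame image-quality metrics and the binary quality gate.
#
# Blurriness is the population variance of the discrete Laplacian of the
# Gaussian-smoothed frame: sharp speckle yields a high variance, motion blur
# a low one. Brightness is the mean intensity on the 0-255 scale. A frame
# enters the pooled malignancy score only when both metrics fall inside
# their operating ranges.

# Reflect-pad a matrix by r rows/cols on each side (symmetric padding, edge
# pixel included), so border filtering does not fabricate dark rims.
reflect_pad <- function(x, r) {
  if (r == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  ri <- c(pmin(r:1, n), 1:n, n + 1 - pmin(1:r, n))
  ci <- c(pmin(r:1, m), 1:m, m + 1 - pmin(1:r, m))
  x[ri, ci, drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a frame
#'
#' Convolves the frame with a normalized Gaussian kernel truncated at radius
#' `ceiling(3 * sigma)`, using reflective boundary handling. The 2-D kernel
#' separates, so the convolution is applied as two 1-D passes; the result is
#' identical to dense 2-D convolution with the normalized product kernel.
#'
#' @param frame Numeric matrix.
#' @param sigma Positive standard deviation of the Gaussian, in pixels.
#' @return Real-valued matrix of the same size (not re-quantized).
#' @export
gaussian_smooth <- function(frame, sigma) {
  frame <- as_frame_matrix(frame)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  p <- reflect_pad(frame, r)
  n <- nrow(frame); m <- ncol(frame)
  # horizontal pass
  h <- matrix(0, n + 2 * r, m)
  for (j in seq_along(k)) {
    h <- h + k[j] * p[, j:(j + m - 1L), drop = FALSE]
  }
  # vertical pass
  out <- matrix(0, n, m)
  for (i in seq_along(k)) {
    out <- out + k[i] * h[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

# Discrete Laplacian, 4-neighbour stencil [[0,1,0],[1,-4,1],[0,1,0]],
# reflective boundaries.
laplacian_filter <- function(x) {
  p <- reflect_pad(x, 1L)
  n <- nrow(x); m <- ncol(x)
  p[1:n, 2:(m + 1)] + p[3:(n + 2), 2:(m + 1)] +
    p[2:(n + 1), 1:m] + p[2:(n + 1), 3:(m + 2)] - 4 * x
}

#' Blurriness score (variance of the Laplacian)
#'
#' Smooths the frame with [gaussian_smooth()], applies the 4-neighbour
#' discrete Laplacian, and returns the population variance (divide by pixel
#' count) of the response. Low values indicate blur; sharp, speckle-rich
#' frames score high.
#'
#' @inheritParams gaussian_smooth
#' @param sigma Gaussian standard deviation used before the Laplacian
#'   (default 1).
#' @return Non-negative scalar.
#' @export
blurriness_score <- function(frame, sigma = 1) {
  lap <- laplacian_filter(gaussian_smooth(frame, sigma))
  mean((lap - mean(lap))^2)
}

#' Brightness score
#'
#' Mean pixel intensity of the frame on the 0-255 scale. Dark, shadowed
#' frames score low; over-gained frames score high.
#'
#' @inheritParams gaussian_smooth
#' @return Non-negative scalar.
#' @export
brightness_score <- function(frame) {
  mean(as_frame_matrix(frame))
}

#' Quality-gate thresholds
#'
#' Operating ranges for the two quality metrics. A frame passes the gate
#' when brightness lies in `[brightness_min, brightness_max]` (closed) and
#' blurriness lies in `[blur_min, blur_max)` (half-open: scores at or above
#' `blur_max` are excluded, matching the rule that frames with blurriness
#' below 200 or at/above 300 are ignored).
#'
#' @param brightness_min,brightness_max Closed brightness interval
#'   (defaults 10 and 30, intensity units).
#' @param blur_min,blur_max Half-open blurriness interval
#'   (defaults 200 and 300, variance units).
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(brightness_min = 10, brightness_max = 30,
                               blur_min = 200, blur_max = 300) {
  if (!(brightness_min < brightness_max)) {
    stop("brightness_min must be < brightness_max", call. = FALSE)
  }
  if (!(blur_min < blur_max)) stop("blur_min must be < blur_max", call. = FALSE)
  structure(
    list(
      brightness_min = brightness_min, brightness_max = brightness_max,
      blur_min = blur_min, blur_max = blur_max
    ),
    class = "quality_thresholds"
  )
}

# gate = 1 iff brightness in [bmin, bmax] AND blurriness in [blmin, blmax)
quality_gate <- function(brightness, blurriness, thresholds) {
  as.integer(
    brightness >= thresholds$brightness_min &
      brightness <= thresholds$brightness_max &
      blurriness >= thresholds$blur_min &
      blurriness < thresholds$blur_max
  )
}

#' Assess a single frame's quality
#'
#' @inheritParams gaussian_smooth
#' @param thresholds A [quality_thresholds()] object.
#' @param sigma Gaussian sigma for the blurriness metric (default 1).
#' @return A list with `brightness`, `blurriness` and binary `gate`.
#' @export
assess_frame <- function(frame, thresholds = quality_thresholds(), sigma = 1) {
  b <- brightness_score(frame)
  bl <- blurriness_score(frame, sigma)
  list(brightness = b, blurriness = bl, gate = quality_gate(b, bl, thresholds))
}

#' Per-frame quality table for a sequence
#'
#' Computes brightness, blurriness and the quality gate for every frame of a
#' sequence. By default metrics are computed on the frames at their native
#' (pre-resize) resolution, because resizing rescales the Laplacian-variance
#' units the thresholds are expressed in; set `quality_on_resized = TRUE` to
#' use the model-geometry frames instead.
#'
#' @param sequence A [bus_sequence()].
#' @param thresholds A [quality_thresholds()] object.
#' @param sigma Gaussian sigma for the blurriness metric.
#' @param quality_on_resized Use resized frames rather than native ones.
#' @return A tibble with columns `sequence_id`, `frame_index`, `brightness`,
#'   `blurriness`, `gate`.
#' @export
assess_sequence <- function(sequence, thresholds = quality_thresholds(),
                            sigma = 1, quality_on_resized = FALSE) {
  stopifnot(inherits(sequence, "bus_sequence"))
  frames <- if (quality_on_resized) sequence$frames else sequence$native_frames
  rows <- purrr::imap(frames, function(f, i) {
    q <- assess_frame(f, thresholds, sigma)
    tibble::tibble(
      sequence_id = sequence$sequence_id, frame_index = i - 1L,
      brightness = q$brightness, blurriness = q$blurriness, gate = q$gate
    )
  })
  dplyr::bind_rows(rows)
}
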