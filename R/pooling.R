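# Quality-gated pooling of per-frame malignancy scores.
#
# The sequence score is S_M = (1/N_q) * sum_i w_i * s_i, where s_i is the
# malignancy score of frame i, w_i is its binary quality gate, and N_q is
# the number of frames passing the gate. Sequences where every frame fails
# the gate fall back to the unweighted mean and are flagged low-confidence.

#' Pool per-frame malignancy scores with quality gates
#'
#' Computes the gated mean of the frame scores. When at least one frame
#' passes the gate the result is the average of the gated scores; when every
#' gate is zero the gated mean is undefined, so the unweighted mean of all
#' frame scores is returned instead and the fallback is signalled through
#' the `"fallback"` attribute (a clinical tool must emit a score for every
#' sequence).
#'
#' @param frame_scores Numeric vector of per-frame scores in \[0, 1\].
#' @param gates Binary vector (0/1) of the same length.
#' @return The pooled score, with attribute `fallback` (TRUE when all gates
#'   were zero).
#' @export
pool_malignancy <- function(frame_scores, gates) {
  if (length(frame_scores) == 0L) {
    stop("cannot pool an empty score vector", call. = FALSE)
  }
  if (length(frame_scores) != length(gates)) {
    stop("`frame_scores` and `gates` must have equal length", call. = FALSE)
  }
  if (anyNA(frame_scores) || min(frame_scores) < 0 || max(frame_scores) > 1) {
    stop("frame scores must lie in [0, 1]", call. = FALSE)
  }
  if (!all(gates %in% c(0, 1))) {
    stop("gates must be binary (0 or 1)", call. = FALSE)
  }
  n_quality <- sum(gates)
  if (n_quality >= 1) {
    structure(sum(gates * frame_scores) / n_quality, fallback = FALSE)
  } else {
    structure(mean(frame_scores), fallback = TRUE)
  }
}

#' Classify a pooled malignancy score
#'
#' A sequence is called malignant when its pooled score is greater than or
#' equal to the decision threshold, benign otherwise (ties go to malignant).
#'
#' @param pooled_score Score in \[0, 1\].
#' @param threshold Decision threshold in \[0, 1\] (default 0.5).
#' @return `"malignant"` or `"benign"`.
#' @export
classify_score <- function(pooled_score, threshold = 0.5) {
  stopifnot(pooled_score >= 0, pooled_score <= 1, threshold >= 0, threshold <= 1)
  if (pooled_score >= threshold) "malignant" else "benign"
}

#' Score a BUS sequence with quality-gated pooling
#'
#' Runs a frame scorer over every frame of the sequence, assesses per-frame
#' quality, pools the scores with [pool_malignancy()] and applies the
#' decision threshold. The result is flagged low-confidence when no frame
#' passed the quality gate or when the pooled score lies within `margin` of
#' the threshold.
#'
#' @param sequence A [bus_sequence()].
#' @param scorer Function mapping a frame matrix (model geometry) to a
#'   malignancy score in \[0, 1\]; see [frame_scorer()].
#' @param thresholds A [quality_thresholds()] object.
#' @param threshold Decision threshold in \[0, 1\] (default 0.5).
#' @param sigma Gaussian sigma for the blurriness metric.
#' @param quality_on_resized Compute quality on the resized frames rather
#'   than the native-resolution ones.
#' @param margin Half-width of the low-confidence band around the threshold
#'   (default 0.05).
#' @return An object of class `malignancy_result` with a per-frame tibble
#'   (`frames`), the pooled score, the predicted label and bookkeeping
#'   fields; see [tidy.malignancy_result()] and [glance.malignancy_result()].
#' @export
score_sequence <- function(sequence, scorer,
                           thresholds = quality_thresholds(),
                           threshold = 0.5, sigma = 1,
                           quality_on_resized = FALSE, margin = 0.05) {
  stopifnot(inherits(sequence, "bus_sequence"), is.function(scorer))
  scores <- vapply(sequence$frames, function(f) {
    s <- scorer(f)
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
      stop("scorer must return a single score in [0, 1]", call. = FALSE)
    }
    as.numeric(s)
  }, numeric(1))
  quality <- assess_sequence(sequence, thresholds, sigma, quality_on_resized)
  pooled <- pool_malignancy(scores, quality$gate)
  fallback <- attr(pooled, "fallback")
  pooled <- as.numeric(pooled)
  result <- list(
    sequence_id = sequence$sequence_id,
    label = sequence$label,
    frames = tibble::tibble(
      index = quality$frame_index,
      score = scores,
      brightness = quality$brightness,
      blurriness = quality$blurriness,
      gate = quality$gate
    ),
    n_frames = length(scores),
    n_quality = sum(quality$gate),
    pooled_score = pooled,
    threshold = threshold,
    sigma = sigma,
    predicted_label = classify_score(pooled, threshold),
    low_confidence = fallback || abs(pooled - threshold) < margin
  )
  structure(result, class = "malignancy_result")
}

#' @export
print.malignancy_result <- function(x, ...) {
  cat(sprintf(
    "<malignancy_result '%s': S_M = %.4f -> %s (N = %d, N_q = %d%s)>\n",
    x$sequence_id, x$pooled_score, x$predicted_label,
    x$n_frames, x$n_quality,
    if (isTRUE(x$low_confidence)) ", low confidence" else ""
  ))
  invisible(x)
}

#' Tidy a malignancy result into a per-frame tibble
#'
#' @param x A `malignancy_result`.
#' @param ... Unused.
#' @return Tibble with one row per frame: `sequence_id`, `index`, `score`,
#'   `brightness`, `blurriness`, `gate`.
#' @export
tidy.malignancy_result <- function(x, ...) {
  dplyr::mutate(x$frames, sequence_id = x$sequence_id, .before = 1)
}

#' One-row summary of a malignancy result
#'
#' @param x A `malignancy_result`.
#' @param ... Unused.
#' @return One-row tibble: `sequence_id`, `label`, `pooled_score`,
#'   `predicted_label`, `n_frames`, `n_quality`, `threshold`,
#'   `low_confidence`.
#' @export
glance.malignancy_result <- function(x, ...) {
  tibble::tibble(
    sequence_id = x$sequence_id,
    label = if (is.null(x$label)) NA_character_ else x$label,
    pooled_score = x$pooled_score,
    predicted_label = x$predicted_label,
    n_frames = x$n_frames,
    n_quality = x$n_quality,
    threshold = x$threshold,
    low_confidence = x$low_confidence
  )
}

#' Plot per-frame malignancy scores of a scored sequence
#'
#' Frame scores are drawn against frame index; frames that failed the
#' quality gate are hollow, and the decision threshold and pooled score are
#' drawn as horizontal lines.
#'
#' @param object A `malignancy_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.malignancy_result <- function(object, ...) {
  df <- tidy(object)
  df$gated <- factor(ifelse(df$gate == 1, "kept", "gated out"),
    levels = c("kept", "gated out")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$score)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$pooled_score, colour = "red3") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0),
      colour = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$gated), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(kept = 16, `gated out` = 1)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "frame index", y = "malignancy score", shape = NULL,
      title = sprintf(
        "%s: S_M = %.3f (%s)", object$sequence_id,
        object$pooled_score, object$predicted_label
      )
    ) +
    ggplot2::theme_minimal()
}
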