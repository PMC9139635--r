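# Grad-CAM: gradient-weighted class activation maps for the classifier.
#
# The neuron importance of channel k is the global average of the gradient
# of the target class's pre-softmax score over that channel's feature map;
# the localization map is the ReLU of the importance-weighted sum of the
# forward activations.

#' Neuron importance weights from gradients
#'
#' Global-average-pools the gradient of the class score over each channel's
#' spatial extent: `beta_k = mean_ij d(y_c) / d(A_k[i, j])`.
#'
#' @param gradients Numeric (u, v, K) array of gradients at the hooked
#'   layer (spatial dims first, channels last).
#' @return Numeric vector of length K.
#' @export
neuron_importance <- function(gradients) {
  if (length(dim(gradients)) != 3L || any(dim(gradients) == 0L)) {
    stop("`gradients` must be a non-empty 3-D array (u, v, channels)",
      call. = FALSE
    )
  }
  apply(gradients, 3, mean)
}

#' Grad-CAM localization map from activations and importances
#'
#' `M = ReLU(sum_k beta_k * A_k)`, elementwise over the spatial grid.
#'
#' @param activations Numeric (u, v, K) array of forward activations.
#' @param weights Numeric vector of K neuron importances
#'   (see [neuron_importance()]).
#' @return Non-negative (u, v) matrix.
#' @export
gradcam_map <- function(activations, weights) {
  d <- dim(activations)
  if (length(d) != 3L) {
    stop("`activations` must be a 3-D array (u, v, channels)", call. = FALSE)
  }
  if (d[3] != length(weights)) {
    stop("channel count of activations does not match length of weights",
      call. = FALSE
    )
  }
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + weights[k] * activations[, , k]
  pmax(m, 0)
}

#' Grad-CAM explanation of a frame
#'
#' Computes the gradient of the target class's pre-softmax score with
#' respect to the activations of the last convolutional stage (the output
#' of the final stage-4 block), applies the importance pooling and ReLU
#' combination, and bilinearly upsamples the map to the input resolution.
#'
#' @param model A `convnext_model`.
#' @param frame Frame matrix at the model geometry (resized if not).
#' @param target_class `"malignant"` (default) or `"benign"`.
#' @return An object of class `gradcam_map` with fields `values` (u x v raw
#'   map), `upsampled` (input-resolution map), `weights`, `frame`,
#'   `target_class`, `layer_id`, `score` (softmax probability of the
#'   malignant class).
#' @export
explain_frame <- function(model, frame, target_class = "malignant") {
  stopifnot(inherits(model, "convnext_model"))
  target_class <- normalize_label(target_class)
  frame <- resize_frame(as_frame_matrix(frame), model$config$input_size)
  target <- if (target_class == "malignant") 1L else 0L
  out <- cn_stage4_grad(frame / 255, model$params, model$config, target)
  beta <- neuron_importance(out$gradients)
  map <- gradcam_map(out$activations, beta)
  up <- EBImage::imageData(EBImage::resize(
    EBImage::Image(map),
    w = model$config$input_size, h = model$config$input_size,
    filter = "bilinear"
  ))
  up <- pmax(up, 0)
  probs <- softmax_rows(matrix(out$logits, nrow = 1))
  depth4 <- model$config$stage_depths[4]
  structure(
    list(
      values = map, upsampled = up, weights = beta, frame = frame,
      target_class = target_class,
      layer_id = sprintf("stage4.block%d.out", depth4),
      score = probs[1, 2]
    ),
    class = "gradcam_map"
  )
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf(
    "<gradcam_map: %dx%d at '%s', target '%s', malignancy score %.3f>\n",
    nrow(x$values), ncol(x$values), x$layer_id, x$target_class, x$score
  ))
  invisible(x)
}

#' Tidy a Grad-CAM map into a long tibble
#'
#' @param x A `gradcam_map`.
#' @param upsampled Return the input-resolution map (default TRUE) rather
#'   than the raw stage-resolution one.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `value`.
#' @export
tidy.gradcam_map <- function(x, upsampled = TRUE, ...) {
  m <- if (upsampled) x$upsampled else x$values
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Overlay plot of a Grad-CAM explanation
#'
#' Renders the frame in grayscale with the class activation map blended on
#' top (blue = low contribution, red = high; per-image min-max scaling is
#' used for display only) and annotates the malignancy score.
#'
#' @param object A `gradcam_map`.
#' @param alpha Maximum overlay opacity (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradcam_map <- function(object, alpha = 0.5, ...) {
  img <- tidy(object)
  img$intensity <- as.vector(object$frame) / 255
  rng <- range(img$value)
  h <- if (diff(rng) > 0) (img$value - rng[1]) / diff(rng) else img$value * 0
  heat_r <- pmin(pmax(1.5 * h - 0.25, 0), 1)
  heat_g <- pmin(pmax(1 - abs(2 * h - 1), 0), 1)
  heat_b <- pmin(pmax(1.25 - 1.5 * h, 0), 1)
  img$blend <- grDevices::rgb(
    (1 - alpha) * img$intensity + alpha * heat_r,
    (1 - alpha) * img$intensity + alpha * heat_g,
    (1 - alpha) * img$intensity + alpha * heat_b
  )
  ggplot2::ggplot(img, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$blend)) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      title = sprintf(
        "Grad-CAM (%s): malignancy score %.3f",
        object$target_class, object$score
      ),
      x = NULL, y = NULL
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Write the raw Grad-CAM map as a plain-text matrix
#'
#' @param x A `gradcam_map`.
#' @param path Output file.
#' @param upsampled Write the input-resolution map (default FALSE: raw
#'   stage-resolution values).
#' @return `path`, invisibly.
#' @export
write_gradcam_matrix <- function(x, path, upsampled = FALSE) {
  m <- if (upsampled) x$upsampled else x$values
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(m, path,
    row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(path)
}

#' Write a Grad-CAM overlay as a PNG image
#'
#' Blends a heat colormap (blue -> red) over the grayscale frame using
#' per-image min-max scaling of the map, and writes an RGB PNG.
#'
#' @param x A `gradcam_map`.
#' @param path Output PNG file.
#' @param alpha Overlay opacity in \[0, 1\] (default 0.5).
#' @return `path`, invisibly.
#' @export
write_gradcam_overlay <- function(x, path, alpha = 0.5) {
  base <- x$frame / 255
  m <- x$upsampled
  rng <- range(m)
  h <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  # simple cold-to-hot map: blue (low) -> red (high)
  heat_r <- pmin(pmax(1.5 * h - 0.25, 0), 1)
  heat_g <- pmin(pmax(1 - abs(2 * h - 1), 0), 1)
  heat_b <- pmin(pmax(1.25 - 1.5 * h, 0), 1)
  rgb <- array(0, dim = c(nrow(base), ncol(base), 3))
  rgb[, , 1] <- (1 - alpha) * base + alpha * heat_r
  rgb[, , 2] <- (1 - alpha) * base + alpha * heat_g
  rgb[, , 3] <- (1 - alpha) * base + alpha * heat_b
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
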