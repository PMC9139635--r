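# Frame and sequence containers.
#
# A frame is a plain numeric matrix (rows = image rows) with intensities on
# the 0-255 grayscale. A sequence bundles an ordered list of frames with
# provenance and an optional ground-truth label.

#' Construct a BUS frame
#'
#' Validates and tags a single-channel ultrasound frame. Frames are ordinary
#' numeric matrices with intensities in \[0, 255\]; this constructor attaches
#' the in-sequence index and the source path as attributes so downstream
#' results can reference them.
#'
#' @param pixels Numeric matrix, intensities in \[0, 255\], at least 8x8.
#' @param index Non-negative integer position of the frame in its sequence.
#' @param source Optional character path the frame was read from.
#' @return The validated matrix with class `bus_frame` and attributes
#'   `index` and `source`.
#' @export
bus_frame <- function(pixels, index = 0L, source = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("frame must be at least 8x8 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  if (index < 0) stop("`index` must be non-negative", call. = FALSE)
  structure(pixels,
    class = c("bus_frame", class(pixels)),
    index = as.integer(index), source = source
  )
}

# Accept either a bus_frame or a bare matrix; validate lightly.
as_frame_matrix <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("a frame must be a numeric matrix", call. = FALSE)
  }
  frame
}

#' Construct a BUS sequence
#'
#' @param frames List of frames (numeric matrices), all with identical
#'   dimensions, in temporal order.
#' @param sequence_id Character identifier (typically the directory name).
#' @param label Optional ground-truth label, `"benign"` or `"malignant"`.
#' @param native_frames Optional list of the same frames at their original
#'   (pre-resize) resolution; kept so quality metrics can be computed on the
#'   native geometry. Defaults to `frames`.
#' @return An object of class `bus_sequence`.
#' @export
bus_sequence <- function(frames, sequence_id = "sequence", label = NULL,
                         native_frames = frames) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("a sequence needs at least one frame", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames in a sequence must share the same dimensions", call. = FALSE)
  }
  label <- normalize_label(label, allow_null = TRUE)
  structure(
    list(
      frames = frames, native_frames = native_frames,
      sequence_id = sequence_id, label = label
    ),
    class = "bus_sequence"
  )
}

normalize_label <- function(label, allow_null = FALSE) {
  if (is.null(label) || (length(label) == 1L && is.na(label))) {
    if (allow_null) return(NULL)
    stop("label must be 'benign' or 'malignant'", call. = FALSE)
  }
  label <- tolower(trimws(as.character(label)))
  bad <- !label %in% c("benign", "malignant")
  if (any(bad)) {
    stop(
      "unknown label: ", paste(unique(label[bad]), collapse = ", "),
      " (expected 'benign' or 'malignant')",
      call. = FALSE
    )
  }
  label
}

#' @export
print.bus_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(
    sprintf(
      "<bus_sequence '%s': %d frame(s) of %dx%d, label: %s>\n",
      x$sequence_id, length(x$frames), d[1], d[2],
      if (is.null(x$label)) "unknown" else x$label
    )
  )
  invisible(x)
}

#' @export
length.bus_sequence <- function(x) length(x$frames)
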