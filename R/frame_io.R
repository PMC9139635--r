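# Reading and writing sequences, manifests and result documents.

# Natural-order sort key: lexicographic with numeric runs compared by value,
# so frame2.png < frame10.png regardless of zero padding.
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  order(keys, x, method = "radix")
}

image_file_pattern <- "\\.(png|tif|tiff|jpg|jpeg)$"

# Read one image file into a grayscale matrix on the 0-255 scale. Color
# inputs are collapsed with the standard luminance weights.
read_frame_file <- function(path) {
  lower <- tolower(path)
  img <- tryCatch(
    {
      if (grepl("\\.png$", lower)) {
        png::readPNG(path)
      } else if (grepl("\\.tiff?$", lower)) {
        tiff::readTIFF(path)
      } else {
        # jpeg and anything else EBImage understands
        EBImage::imageData(EBImage::readImage(path))
      }
    },
    error = function(e) {
      stop("could not read image file '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  pmin(pmax(img * 255, 0), 255)
}

# Bilinear resize of a grayscale matrix to size x size.
resize_frame <- function(frame, size) {
  if (nrow(frame) == size && ncol(frame) == size) return(frame)
  out <- EBImage::resize(EBImage::Image(frame / 255), w = size, h = size,
    filter = "bilinear"
  )
  pmin(pmax(EBImage::imageData(out) * 255, 0), 255)
}

#' Load a BUS sequence from a directory of image files
#'
#' Reads every PNG/TIFF/JPEG file in `directory` in natural filename order
#' (numeric runs compared by value), converts color inputs to grayscale with
#' luminance weights 0.299/0.587/0.114, and resizes each frame to
#' `target_size` x `target_size` by bilinear interpolation. The native-
#' resolution frames are retained alongside the resized ones so quality
#' metrics can be computed on the original geometry.
#'
#' @param directory Path to a directory containing the frames of one
#'   sequence.
#' @param target_size Working geometry of the classifier (default 224).
#' @param label Optional ground-truth label for the sequence.
#' @return A [bus_sequence()] whose `frames` are `target_size`-sized and
#'   whose `native_frames` hold the original resolution.
#' @export
load_sequence <- function(directory, target_size = 224, label = NULL) {
  if (!dir.exists(directory)) {
    stop("sequence directory '", directory, "' does not exist", call. = FALSE)
  }
  files <- list.files(directory, pattern = image_file_pattern,
    ignore.case = TRUE, full.names = TRUE
  )
  if (length(files) == 0L) {
    stop("no frames: directory '", directory, "' contains no image files",
      call. = FALSE
    )
  }
  files <- files[natural_order(basename(files))]
  native <- lapply(files, read_frame_file)
  frames <- lapply(native, resize_frame, size = target_size)
  seq <- bus_sequence(frames,
    sequence_id = basename(normalizePath(directory)),
    label = label, native_frames = native
  )
  seq$sources <- files
  seq
}

#' Load a sequence manifest
#'
#' Reads a CSV with header columns `sequence_directory,label,split` that
#' assigns a ground-truth label and a train/val/test split to each sequence
#' directory. Labels are normalized to lowercase and validated.
#'
#' @param csv_path Path to the manifest CSV (UTF-8, comma-separated).
#' @param check_dirs Verify that every referenced directory exists and
#'   contains at least one readable image file (default TRUE).
#' @param base_dir Directory that relative `sequence_directory` entries are
#'   resolved against (default: the manifest's directory).
#' @return A tibble with columns `sequence_directory`, `label`, `split`.
#' @export
load_manifest <- function(csv_path, check_dirs = TRUE,
                          base_dir = dirname(csv_path)) {
  if (!file.exists(csv_path)) {
    stop("manifest '", csv_path, "' does not exist", call. = FALSE)
  }
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  required <- c("sequence_directory", "label", "split")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df$label <- normalize_label(df$label)
  df$split <- tolower(trimws(df$split))
  bad_split <- !df$split %in% c("train", "val", "test")
  if (any(bad_split)) {
    stop("unknown split token(s): ",
      paste(unique(df$split[bad_split]), collapse = ", "),
      call. = FALSE
    )
  }
  df$sequence_directory <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$sequence_directory),
    df$sequence_directory,
    file.path(base_dir, df$sequence_directory)
  )
  if (check_dirs) {
    for (d in df$sequence_directory) {
      if (!dir.exists(d)) {
        stop("manifest references missing directory '", d, "'", call. = FALSE)
      }
      n <- length(list.files(d, pattern = image_file_pattern, ignore.case = TRUE))
      if (n == 0L) {
        stop("manifest directory '", d, "' contains no image files",
          call. = FALSE
        )
      }
    }
  }
  tibble::as_tibble(df[, required])
}

#' Write a malignancy result to JSON
#'
#' Serializes a [score_sequence()] result as a JSON document with one record
#' per frame (index, score, brightness, blurriness, gate) and a sequence
#' summary (pooled score, N, N_q, predicted label, threshold, sigma,
#' low-confidence flag). Numbers are written at full precision so a
#' round-trip via [read_result()] reproduces the pooled score bit-exactly.
#'
#' @param result A `malignancy_result` from [score_sequence()].
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_result <- function(result, out_path) {
  stopifnot(inherits(result, "malignancy_result"))
  doc <- list(
    sequence_id = result$sequence_id,
    frames = result$frames,
    summary = list(
      pooled_score = result$pooled_score,
      n_frames = result$n_frames,
      n_quality = result$n_quality,
      predicted_label = result$predicted_label,
      threshold = result$threshold,
      sigma = result$sigma,
      low_confidence = result$low_confidence
    )
  )
  if (!is.null(result$label)) doc$label <- result$label
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  # I(17) significant digits: enough for doubles to round-trip bit-exactly
  jsonlite::write_json(doc, out_path,
    auto_unbox = TRUE, digits = I(17), dataframe = "rows", pretty = TRUE
  )
  invisible(out_path)
}

#' Read a malignancy result written by [write_result()]
#'
#' @param path Path to the JSON document.
#' @return A `malignancy_result` object.
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- list(
    sequence_id = doc$sequence_id,
    label = doc$label,
    frames = tibble::as_tibble(doc$frames),
    n_frames = doc$summary$n_frames,
    n_quality = doc$summary$n_quality,
    pooled_score = doc$summary$pooled_score,
    threshold = doc$summary$threshold,
    sigma = doc$summary$sigma,
    predicted_label = doc$summary$predicted_label,
    low_confidence = doc$summary$low_confidence
  )
  structure(res, class = "malignancy_result")
}

#' Write a frame as an 8-bit grayscale PNG
#'
#' @param frame Numeric matrix with intensities in \[0, 255\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  frame <- as_frame_matrix(frame)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(round(frame) / 255, path)
  invisible(path)
}
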