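# ConvNeXt classifier: configuration, initialization, forward passes and
# checkpoints. The numerical kernels live in src/convnext_ops.cpp; this file
# owns parameter layout, initialization and the user-facing API.

#' ConvNeXt configuration
#'
#' Describes the multistage ConvNeXt classifier: a patchify stem
#' (`patch_size` x `patch_size` convolution with stride `patch_stride`),
#' four stages of residual blocks with per-stage depths and widths,
#' LayerNorm + 2x2 stride-2 downsampling between stages, and a global
#' average pool + LayerNorm + linear head.
#'
#' @param stage_depths Four block counts, one per stage (default `(3,4,6,3)`,
#'   the stage-compute-ratio of the reference design).
#' @param stage_widths Four channel widths (default `(96,192,384,768)`; see
#'   [convnext_tiny_test_config()] for the desk-scale preset).
#' @param patch_size,patch_stride Stem convolution kernel and stride
#'   (default 4 and 4, the "patchify" stem).
#' @param dw_kernel Depthwise convolution kernel size, odd (default 7).
#' @param expansion_ratio Hidden expansion of the inverted bottleneck
#'   (default 4).
#' @param num_classes Output classes (default 2: benign, malignant).
#' @param norm_epsilon LayerNorm epsilon added to the standard deviation
#'   (default 1e-6).
#' @param gelu_mode `"exact"` (z * Phi(z)) or `"tanh"` (the cubic tanh
#'   approximation).
#' @param input_size Working image size (default 224). Must be divisible by
#'   `patch_stride * 8` so the three downsamplings stay integral.
#' @param input_norm How frames are normalized before entering the stem:
#'   `"scale"` divides by 255; `"standardize"` z-scores each frame (making
#'   the classifier invariant to global gain). Default `"scale"`.
#' @return An object of class `convnext_config`.
#' @export
convnext_config <- function(stage_depths = c(3L, 4L, 6L, 3L),
                            stage_widths = c(96L, 192L, 384L, 768L),
                            patch_size = 4L, patch_stride = 4L,
                            dw_kernel = 7L, expansion_ratio = 4L,
                            num_classes = 2L, norm_epsilon = 1e-6,
                            gelu_mode = c("exact", "tanh"),
                            input_size = 224L,
                            input_norm = c("scale", "standardize")) {
  gelu_mode <- match.arg(gelu_mode)
  input_norm <- match.arg(input_norm)
  stopifnot(
    length(stage_depths) == 4L, all(stage_depths >= 1L),
    length(stage_widths) == 4L, all(stage_widths >= 1L),
    patch_size >= 1L, patch_stride >= 1L, expansion_ratio >= 1L,
    num_classes >= 1L, norm_epsilon > 0
  )
  if (dw_kernel %% 2L != 1L) stop("`dw_kernel` must be odd", call. = FALSE)
  if (input_size %% (patch_stride * 8L) != 0L) {
    stop("`input_size` must be divisible by patch_stride * 8 ",
      "(stem stride followed by three 2x downsamplings)",
      call. = FALSE
    )
  }
  structure(
    list(
      stage_depths = as.integer(stage_depths),
      stage_widths = as.integer(stage_widths),
      patch_size = as.integer(patch_size),
      patch_stride = as.integer(patch_stride),
      dw_kernel = as.integer(dw_kernel),
      expansion_ratio = as.integer(expansion_ratio),
      num_classes = as.integer(num_classes),
      norm_epsilon = norm_epsilon,
      gelu_mode = gelu_mode,
      input_size = as.integer(input_size),
      input_norm = input_norm
    ),
    class = "convnext_config"
  )
}

#' Desk-scale ConvNeXt preset
#'
#' Same depths and topology as the default configuration but with narrow
#' stages `(16, 32, 64, 128)` and a 64-pixel working geometry, small enough
#' to train on a laptop CPU in minutes. Used throughout the test suite and
#' the synthetic end-to-end experiment.
#'
#' @param input_size Working image size (default 64).
#' @param ... Passed on to [convnext_config()].
#' @return A `convnext_config`.
#' @export
convnext_tiny_test_config <- function(input_size = 64L, ...) {
  convnext_config(
    stage_widths = c(16L, 32L, 64L, 128L),
    input_size = input_size, ...
  )
}

#' Stage spatial sizes implied by a configuration
#'
#' @param config A `convnext_config`.
#' @return Integer vector of the four stage feature-map sizes
#'   (input/4, /8, /16, /32 for the default stem).
#' @export
stage_spatial_sizes <- function(config) {
  s1 <- config$input_size %/% config$patch_stride
  as.integer(s1 %/% c(1L, 2L, 4L, 8L))
}

#' Gaussian error linear unit
#'
#' `gelu(z) = z * Phi(z)` with `Phi` the standard normal CDF (`"exact"`), or
#' the cubic tanh approximation
#' `0.5 z (1 + tanh(sqrt(2/pi) (z + 0.044715 z^3)))` (`"tanh"`).
#'
#' @param z Numeric vector.
#' @param mode `"exact"` or `"tanh"`.
#' @return Numeric vector of the same length.
#' @export
gelu <- function(z, mode = c("exact", "tanh")) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    z * pnorm(z)
  } else {
    0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
  }
}

#' Layer normalization of one hidden-unit vector
#'
#' Normalizes `a` to `(a - mu) / (sigma + epsilon)` where `mu` and `sigma`
#' are the mean and the population standard deviation of the vector, then
#' applies the learnable per-unit scale and shift (identity by default).
#' Statistics are per sample, so the result is independent of any batching.
#'
#' @param a Numeric vector of hidden units (length >= 1).
#' @param epsilon Small positive stabilizer added to sigma (default 1e-6).
#' @param gamma,beta Optional per-unit scale and shift (defaults 1 and 0).
#' @return Normalized numeric vector.
#' @export
layer_norm <- function(a, epsilon = 1e-6, gamma = NULL, beta = NULL) {
  if (length(a) < 1L) stop("`a` must be a non-empty vector", call. = FALSE)
  mu <- mean(a)
  sigma <- sqrt(mean((a - mu)^2))
  xhat <- (a - mu) / (sigma + epsilon)
  if (is.null(gamma)) gamma <- 1
  if (is.null(beta)) beta <- 0
  gamma * xhat + beta
}

# Truncated-normal init (+/- 2 sd), seeded by the caller's RNG state.
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Parameter layout shared with the C++ side. Names must match
# parse_params()/make_grads() in src/convnext_ops.cpp.
init_params <- function(config, residual_zero_init = TRUE) {
  p <- list()
  cw <- config$stage_widths
  k <- config$patch_size
  p[["stem.w"]] <- array(trunc_normal(k * k * cw[1]), dim = c(k, k, 1, cw[1]))
  p[["stem.b"]] <- numeric(cw[1])
  p[["stem.ln.g"]] <- rep(1, cw[1])
  p[["stem.ln.b"]] <- numeric(cw[1])
  dk <- config$dw_kernel
  e <- config$expansion_ratio
  for (s in 1:4) {
    C <- cw[s]
    for (b in seq_len(config$stage_depths[s])) {
      pre <- sprintf("s%d.b%d.", s, b)
      p[[paste0(pre, "dw.w")]] <- array(trunc_normal(dk * dk * C), dim = c(dk, dk, C))
      p[[paste0(pre, "dw.b")]] <- numeric(C)
      p[[paste0(pre, "ln.g")]] <- rep(1, C)
      p[[paste0(pre, "ln.b")]] <- numeric(C)
      p[[paste0(pre, "pw1.w")]] <- matrix(trunc_normal(C * e * C), C, e * C)
      p[[paste0(pre, "pw1.b")]] <- numeric(e * C)
      # final projection can start at zero: every residual branch then
      # begins as the identity and fades in during training (the
      # stabilizing role LayerScale plays in the reference design)
      p[[paste0(pre, "pw2.w")]] <- if (residual_zero_init) {
        matrix(0, e * C, C)
      } else {
        matrix(trunc_normal(e * C * C), e * C, C)
      }
      p[[paste0(pre, "pw2.b")]] <- numeric(C)
    }
  }
  for (i in 1:3) {
    pre <- sprintf("ds%d.", i)
    p[[paste0(pre, "ln.g")]] <- rep(1, cw[i])
    p[[paste0(pre, "ln.b")]] <- numeric(cw[i])
    p[[paste0(pre, "w")]] <- array(
      trunc_normal(4 * cw[i] * cw[i + 1]),
      dim = c(2, 2, cw[i], cw[i + 1])
    )
    p[[paste0(pre, "b")]] <- numeric(cw[i + 1])
  }
  p[["head.ln.g"]] <- rep(1, cw[4])
  p[["head.ln.b"]] <- numeric(cw[4])
  # classifier head starts at zero: the logits of a fresh model are exactly
  # equal, so early training has no arbitrary class bias to unlearn (which
  # destabilizes the small-batch Adam recipe)
  p[["head.w"]] <- matrix(0, cw[4], config$num_classes)
  p[["head.b"]] <- numeric(config$num_classes)
  p
}

#' Build a ConvNeXt classifier
#'
#' Initializes all weights (truncated normal, sd 0.02, for convolutions and
#' linear layers; identity LayerNorm affines; zero biases) under the given
#' seed, so two builds with the same seed are identical.
#'
#' @param config A [convnext_config()].
#' @param seed Integer RNG seed for the initialization.
#' @param residual_zero_init Start every block's final projection at zero
#'   so residual branches begin as the identity (default TRUE; see the
#'   methods vignette).
#' @return An object of class `convnext_model` holding the config and a
#'   named list of parameter arrays.
#' @export
build_convnext <- function(config = convnext_config(), seed = 1L,
                           residual_zero_init = TRUE) {
  stopifnot(inherits(config, "convnext_config"))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- init_params(config, residual_zero_init)
  structure(
    list(
      config = config, params = params, seed = as.integer(seed),
      residual_zero_init = residual_zero_init
    ),
    class = "convnext_model"
  )
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.convnext_model <- function(x, ...) {
  cat(sprintf(
    "<convnext_model: depths (%s), widths (%s), input %dx%d, %s parameters>\n",
    paste(x$config$stage_depths, collapse = ","),
    paste(x$config$stage_widths, collapse = ","),
    x$config$input_size, x$config$input_size,
    format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model A `convnext_model`.
#' @return Integer count over all parameter arrays.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# Stack a list of frames into an (H, W, N) array normalized for the stem.
frames_to_batch <- function(frames, input_size, input_norm = "scale") {
  arr <- array(0, dim = c(input_size, input_size, length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (nrow(f) != input_size || ncol(f) != input_size) {
      stop(sprintf(
        "frame is %dx%d but the model expects %dx%d",
        nrow(f), ncol(f), input_size, input_size
      ), call. = FALSE)
    }
    arr[, , i] <- if (identical(input_norm, "standardize")) {
      (f - mean(f)) / max(stats::sd(f), 1e-6)
    } else {
      f / 255
    }
  }
  arr
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Class probabilities for a list of frames
#'
#' @param model A `convnext_model`.
#' @param frames List of frame matrices at the model's working geometry.
#' @return Matrix (frames x classes) of softmax probabilities; column 2 is
#'   the malignant class.
#' @export
predict_frames <- function(model, frames) {
  x <- frames_to_batch(frames, model$config$input_size,
    model$config$input_norm %||% "scale"
  )
  logits <- cn_logits(x, model$params, model$config)
  softmax_rows(logits)
}

#' Malignancy score of a single frame
#'
#' Softmax probability of the malignant class under the model, deterministic
#' in evaluation mode (the network has no stochastic layers).
#'
#' @param model A `convnext_model`.
#' @param frame Frame matrix at the model's working geometry.
#' @return Score in \[0, 1\].
#' @export
predict_frame <- function(model, frame) {
  predict_frames(model, list(frame))[1, 2]
}

#' Frame-scoring closure for [score_sequence()]
#'
#' @param model A `convnext_model`.
#' @return A function mapping a frame matrix to its malignancy score,
#'   resizing to the model geometry when needed.
#' @export
frame_scorer <- function(model) {
  force(model)
  function(frame) {
    frame <- resize_frame(as_frame_matrix(frame), model$config$input_size)
    predict_frame(model, frame)
  }
}

#' Single ConvNeXt block forward pass
#'
#' Applies one residual block (depthwise conv -> LayerNorm -> 1x1 expansion
#' -> GELU -> 1x1 projection -> residual add) to an (H, W, C) activation
#' array. Exposed for inspection and testing.
#'
#' @param x Numeric (H, W, C) array.
#' @param block_params Named list with `dw.w` (k,k,C), `dw.b`, `ln.g`,
#'   `ln.b`, `pw1.w` (C, eC), `pw1.b`, `pw2.w` (eC, C), `pw2.b`.
#' @param epsilon LayerNorm epsilon.
#' @param gelu_mode `"exact"` or `"tanh"`.
#' @return (H, W, C) array.
#' @export
convnext_block <- function(x, block_params, epsilon = 1e-6,
                           gelu_mode = "exact") {
  cn_block_forward(
    x, block_params[["dw.w"]], block_params[["dw.b"]],
    block_params[["ln.g"]], block_params[["ln.b"]],
    block_params[["pw1.w"]], block_params[["pw1.b"]],
    block_params[["pw2.w"]], block_params[["pw2.b"]],
    epsilon, identical(gelu_mode, "tanh")
  )
}

checkpoint_format_version <- 1L

#' Save model weights to a checkpoint file
#'
#' The checkpoint embeds the configuration and a format version; loading
#' validates both.
#'
#' @param model A `convnext_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "convnext_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(
    list(
      format = "busnext-checkpoint", version = checkpoint_format_version,
      config = model$config, params = model$params, seed = model$seed
    ),
    path
  )
  invisible(path)
}

#' Load model weights from a checkpoint file
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `convnext_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop("checkpoint not found: '", path, "'", call. = FALSE)
  }
  obj <- readRDS(path)
  if (!identical(obj$format, "busnext-checkpoint")) {
    stop("'", path, "' is not a busnext checkpoint", call. = FALSE)
  }
  if (obj$version > checkpoint_format_version) {
    stop("checkpoint format version ", obj$version, " is newer than supported",
      call. = FALSE
    )
  }
  structure(
    list(config = obj$config, params = obj$params, seed = obj$seed),
    class = "convnext_model"
  )
}
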