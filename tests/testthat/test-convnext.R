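# ConvNeXt backbone: GELU, LayerNorm, block mechanics, architecture
# arithmetic and prediction plumbing.

test_that("gelu exact form matches the normal-CDF definition", {
  expect_equal(gelu(0, "exact"), 0)
  expect_equal(gelu(1, "exact"), 1 * pnorm(1), tolerance = 1e-12)
  expect_equal(gelu(1, "exact"), 0.841345, tolerance = 1e-5)
  z <- seq(-4, 4, length.out = 101)
  expect_equal(gelu(z, "exact"), z * pnorm(z), tolerance = 1e-12)
})

test_that("gelu tanh approximation stays within 1e-2 of the exact form", {
  z <- seq(-5, 5, length.out = 1e4)
  expect_lt(max(abs(gelu(z, "exact") - gelu(z, "tanh"))), 1e-2)
})

test_that("gelu satisfies the reflection identity gelu(z) - gelu(-z) = z", {
  z <- seq(-6, 6, length.out = 501)
  expect_equal(gelu(z, "exact") - gelu(-z, "exact"), z, tolerance = 1e-12)
  expect_equal(gelu(z, "tanh") - gelu(-z, "tanh"), z, tolerance = 1e-12)
})

test_that("layer_norm normalizes mean and variance per sample", {
  expect_equal(layer_norm(c(1, 3)), c(-1, 1), tolerance = 1e-5)
  expect_equal(layer_norm(rep(4.2, 10)), rep(0, 10))
  set.seed(11)
  for (rep in 1:20) {
    a <- rnorm(64, sd = runif(1, 0.5, 5))
    out <- layer_norm(a)
    expect_lt(abs(mean(out)), 1e-6)
    expect_lt(abs(mean((out - mean(out))^2) - 1), 1e-4)
  }
  expect_error(layer_norm(numeric(0)), "non-empty")
})

test_that("layer normalization is independent of batching", {
  # the network normalizes each sample with its own statistics, so a frame
  # scored alone equals the same frame scored inside a batch
  set.seed(22)
  cfg <- test_net_config()
  m <- build_convnext(cfg, seed = 3)
  frames <- replicate(3, matrix(runif(32 * 32, 0, 255), 32, 32), simplify = FALSE)
  batch <- predict_frames(m, frames)
  solo <- t(vapply(frames, function(f) predict_frames(m, list(f))[1, ], numeric(2)))
  expect_equal(batch, solo, tolerance = 1e-12)
})

test_that("configuration validates its invariants", {
  expect_error(convnext_config(dw_kernel = 6), "odd")
  expect_error(convnext_config(input_size = 100), "divisible")
  expect_error(convnext_config(stage_depths = c(1, 1, 1)), "length")
  expect_s3_class(convnext_tiny_test_config(), "convnext_config")
})

test_that("default architecture has the printed block counts and stage sizes", {
  cfg <- convnext_config()
  expect_equal(cfg$stage_depths, c(3L, 4L, 6L, 3L))
  expect_equal(stage_spatial_sizes(cfg), c(56L, 28L, 14L, 7L))
  tiny <- convnext_tiny_test_config()
  expect_equal(stage_spatial_sizes(tiny), c(16L, 8L, 4L, 2L))
})

test_that("a zero-weight block is the identity (residual path)", {
  set.seed(33)
  C <- 5L
  x <- array(rnorm(7 * 7 * C), dim = c(7, 7, C))
  bp <- list(
    "dw.w" = array(0, c(7, 7, C)), "dw.b" = numeric(C),
    "ln.g" = rep(1, C), "ln.b" = numeric(C),
    "pw1.w" = matrix(0, C, 4 * C), "pw1.b" = numeric(4 * C),
    "pw2.w" = matrix(0, 4 * C, C), "pw2.b" = numeric(C)
  )
  out <- convnext_block(x, bp)
  expect_equal(out, x, tolerance = 1e-14)
})

test_that("a block preserves shape and matches a hand-computed forward pass", {
  set.seed(44)
  x <- array(rnorm(28 * 28 * 16), dim = c(28, 28, 16))
  bp <- list(
    "dw.w" = array(rnorm(49 * 16, 0, 0.1), c(7, 7, 16)), "dw.b" = rnorm(16, 0, 0.1),
    "ln.g" = runif(16, 0.5, 1.5), "ln.b" = rnorm(16, 0, 0.1),
    "pw1.w" = matrix(rnorm(16 * 64, 0, 0.1), 16, 64), "pw1.b" = rnorm(64, 0, 0.1),
    "pw2.w" = matrix(rnorm(64 * 16, 0, 0.1), 64, 16), "pw2.b" = rnorm(16, 0, 0.1)
  )
  out <- convnext_block(x, bp)
  expect_equal(dim(out), c(28L, 28L, 16L))

  # independent R forward pass on a small single-position check: the 1x1
  # convolutions act per spatial location, so verify one location end to end
  # on a 1-channel toy block
  x1 <- array(rnorm(5 * 5), dim = c(5, 5, 1))
  w <- array(0, c(7, 7, 1)); w[4, 4, 1] <- 2 # doubles the input
  bp1 <- list(
    "dw.w" = w, "dw.b" = 0.5,
    "ln.g" = 1.3, "ln.b" = -0.2,
    "pw1.w" = matrix(0.7, 1, 4), "pw1.b" = rep(0.1, 4),
    "pw2.w" = matrix(0.25, 4, 1), "pw2.b" = 0.05
  )
  out1 <- convnext_block(x1, bp1, epsilon = 1e-6)
  # hand computation: dwconv -> per-position LN over the single channel
  # (sd = 0 so the normalized value is 0) -> affine -> pw1 -> gelu -> pw2
  # -> residual
  ln_val <- 1.3 * 0 + (-0.2)
  h <- 0.7 * ln_val + 0.1
  act <- h * pnorm(h)
  branch <- 4 * 0.25 * act + 0.05
  expect_equal(as.vector(out1[, , 1]), as.vector(x1[, , 1]) + branch,
    tolerance = 1e-6
  )
})

test_that("model building is seeded and parameter count is config-determined", {
  cfg <- test_net_config()
  m1 <- build_convnext(cfg, seed = 9)
  m2 <- build_convnext(cfg, seed = 9)
  m3 <- build_convnext(cfg, seed = 10)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_equal(n_parameters(m1), n_parameters(m3))

  # doubling widths roughly quadruples the per-block parameter mass
  narrow <- build_convnext(convnext_config(
    stage_depths = c(1, 1, 1, 1), stage_widths = c(8, 16, 32, 64),
    input_size = 32
  ), seed = 1)
  wide <- build_convnext(convnext_config(
    stage_depths = c(1, 1, 1, 1), stage_widths = c(16, 32, 64, 128),
    input_size = 32
  ), seed = 1)
  block_par <- function(m, pre) {
    sum(vapply(
      grep(pre, names(m$params), value = TRUE),
      function(nm) length(m$params[[nm]]), numeric(1)
    ))
  }
  ratio <- block_par(wide, "^s3\\.b1\\.") / block_par(narrow, "^s3\\.b1\\.")
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1 + 0.5)
})

test_that("the patchify stem is translation-consistent at stride granularity", {
  set.seed(55)
  cfg <- test_net_config()
  m <- build_convnext(cfg, seed = 2)
  x <- matrix(runif(40 * 40), 40, 40)
  stem <- function(img) {
    cn_conv2d(
      array(img, dim = c(nrow(img), ncol(img), 1)),
      m$params[["stem.w"]], m$params[["stem.b"]], cfg$patch_size,
      cfg$patch_stride, cfg$stage_widths[1]
    )
  }
  full <- stem(x)
  shifted <- stem(x[5:40, , drop = FALSE]) # shift by one stride (4 px)
  expect_equal(full[2:10, , ], shifted[1:9, , ], tolerance = 1e-12)
})

test_that("predictions are softmax probabilities and deterministic", {
  set.seed(66)
  cfg <- test_net_config()
  m <- build_convnext(cfg, seed = 4)
  f <- matrix(runif(32 * 32, 0, 255), 32, 32)
  p <- predict_frames(m, list(f))
  expect_equal(sum(p[1, ]), 1, tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict_frame(m, f), predict_frame(m, f))

  # zeroed head -> equal logits -> uniform softmax
  m0 <- m
  m0$params[["head.w"]][] <- 0
  m0$params[["head.b"]][] <- 0
  expect_equal(predict_frame(m0, f), 0.5, tolerance = 1e-12)

  expect_error(predict_frame(m, matrix(0, 16, 16)), "expects")
})

test_that("checkpoints round-trip weights and config", {
  cfg <- test_net_config()
  m <- build_convnext(cfg, seed = 12)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_equal(unclass(m2$config), unclass(m$config))
  f <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_identical(predict_frame(m, f), predict_frame(m2, f))
  expect_error(load_checkpoint(tempfile()), "not found")
  unlink(path)
})
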