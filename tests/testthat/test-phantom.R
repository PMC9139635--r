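# Synthetic phantom generator: determinism, morphology, calibration against
# the default quality gates, and dataset writing.

test_that("frame generation is deterministic under a fixed seed", {
  cfg <- phantom_config()
  set.seed(42)
  f1 <- generate_frame(cfg, "malignant")
  set.seed(42)
  f2 <- generate_frame(cfg, "malignant")
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(f1$mask, f2$mask)
})

test_that("frames honor the intensity and geometry invariants", {
  cfg <- phantom_config()
  set.seed(43)
  for (label in c("benign", "malignant")) {
    f <- generate_frame(cfg, label)
    expect_equal(dim(f$pixels), c(64L, 64L))
    expect_true(all(f$pixels >= 0 & f$pixels <= 255))
    expect_true(all(f$pixels == round(f$pixels)))
    expect_true(any(f$mask) && !all(f$mask))
  }
  expect_error(generate_frame(cfg, "cyst"), "unknown label")
})

test_that("the lesion is hypoechoic: darker inside the mask than outside", {
  cfg <- phantom_config()
  set.seed(44)
  gaps <- replicate(100, {
    f <- generate_frame(cfg, sample(c("benign", "malignant"), 1))
    mean(f$pixels[!f$mask]) - mean(f$pixels[f$mask])
  })
  expect_true(all(gaps >= 10))
})

test_that("a strong gain drop defeats the brightness gate", {
  cfg <- phantom_config(gain_prob = 1, gain_range = c(0.2, 0.2))
  set.seed(45)
  f <- generate_frame(cfg, "benign")
  expect_lt(brightness_score(f$pixels), 10)
})

test_that("clean sequences pass the default gates, corrupted frames fail them", {
  cfg <- phantom_config()
  set.seed(46)
  clean_pass <- c()
  corrupt_fail <- c()
  for (rep in 1:20) {
    g <- generate_sequence(cfg, "benign", n_frames = 10, corrupt_fraction = 0.3)
    q <- assess_sequence(g$sequence)
    clean_pass <- c(clean_pass, q$gate[!g$corrupted])
    corrupt_fail <- c(corrupt_fail, 1 - q$gate[g$corrupted])
  }
  expect_gte(mean(clean_pass), 0.95)
  expect_gte(mean(corrupt_fail), 0.90)
})

test_that("corruption counts follow the rounded fraction", {
  cfg <- phantom_config()
  set.seed(47)
  g <- generate_sequence(cfg, "malignant", n_frames = 13, corrupt_fraction = 0.15)
  expect_equal(sum(g$corrupted), 2L) # round(13 * 0.15)
  g0 <- generate_sequence(cfg, "malignant", n_frames = 8, corrupt_fraction = 0)
  expect_equal(sum(g0$corrupted), 0L)
})

test_that("fully corrupted sequences drive pooling into the fallback path", {
  cfg <- phantom_config()
  set.seed(48)
  g <- generate_sequence(cfg, "benign", n_frames = 5, corrupt_fraction = 1)
  res <- score_sequence(g$sequence, function(f) 0.4)
  expect_equal(res$n_quality, 0L)
  expect_true(res$low_confidence)
})

test_that("sequences keep one lesion geometry with per-frame jitter", {
  cfg <- phantom_config()
  set.seed(49)
  g <- generate_sequence(cfg, "malignant", n_frames = 6, corrupt_fraction = 0)
  areas <- vapply(g$masks, sum, numeric(1))
  # same star-convex lesion, only translated: area is stable
  expect_lt(diff(range(areas)) / mean(areas), 0.2)
  centers <- vapply(g$masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2))
  expect_lt(max(centers[1, ]) - min(centers[1, ]), 5)
  expect_lt(max(centers[2, ]) - min(centers[2, ]), 5)
})

test_that("the study split is sequence-level 70/15/15", {
  study <- generate_phantom_study(10, 10, frames_per_sequence = 3, seed = 5)
  expect_equal(nrow(study), 20L)
  counts <- table(study$split, study$label)
  expect_equal(unname(counts["train", "benign"]), 6)
  expect_equal(unname(counts["val", "benign"]), 2)
  expect_equal(unname(counts["test", "benign"]), 2)
  # frame counts and labels propagate into the sequences
  expect_true(all(vapply(study$sequence, length, integer(1)) == 3L))
  expect_identical(
    vapply(study$sequence, function(s) s$label, character(1)),
    study$label
  )
})

test_that("on-disk datasets are byte-reproducible and manifest-complete", {
  d1 <- tempfile("ds1"); d2 <- tempfile("ds2")
  generate_dataset(d1, 2, 2, frames_per_sequence = 3, seed = 11)
  generate_dataset(d2, 2, 2, frames_per_sequence = 3, seed = 11)
  mf <- load_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(mf), 4L)
  expect_equal(sum(mf$label == "benign"), 2L)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(length(grep("\\.png$", f1)), 12L)
  for (f in f1) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
  # a loaded sequence reproduces the generated pixels exactly
  set.seed(1)
  seq <- load_sequence(mf$sequence_directory[1], target_size = 64)
  expect_equal(dim(seq$native_frames[[1]]), c(64L, 64L))
  unlink(c(d1, d2), recursive = TRUE)
  expect_error(generate_dataset(tempfile(), 0, 2), "n_benign")
})
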