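# Sequence/manifest/result I/O.

write_test_sequence <- function(dir, frames) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    write_frame_png(frames[[i]], file.path(dir, sprintf("frame%d.png", i - 1L)))
  }
  dir
}

test_that("load_sequence reads, orders, grays and resizes frames", {
  tmp <- tempfile("seq")
  set.seed(1)
  frames <- replicate(13, round(matrix(runif(32 * 32, 0, 255), 32, 32)),
    simplify = FALSE
  )
  write_test_sequence(tmp, frames)
  seq <- load_sequence(tmp, target_size = 224)
  expect_equal(length(seq), 13L)
  expect_equal(dim(seq$frames[[1]]), c(224L, 224L))
  expect_equal(dim(seq$native_frames[[1]]), c(32L, 32L))
  # natural order: frame2 sorts before frame10
  expect_equal(basename(seq$sources[3]), "frame2.png")
  expect_equal(basename(seq$sources[11]), "frame10.png")
  unlink(tmp, recursive = TRUE)
})

test_that("a constant frame is invariant under bilinear resize", {
  tmp <- tempfile("seq")
  write_test_sequence(tmp, list(matrix(37, 64, 64)))
  seq <- load_sequence(tmp, target_size = 224)
  expect_equal(length(seq), 1L)
  expect_true(all(abs(seq$frames[[1]] - 37) < 0.5 + 1e-9))
  expect_equal(stats::sd(seq$frames[[1]]), 0)
  unlink(tmp, recursive = TRUE)
})

test_that("empty or missing sequence directories raise errors", {
  tmp <- tempfile("empty")
  dir.create(tmp)
  expect_error(load_sequence(tmp), "no frames")
  expect_error(load_sequence(tempfile()), "does not exist")
  unlink(tmp, recursive = TRUE)
})

test_that("color PNG input collapses by luminance weights", {
  tmp <- tempfile("seqc")
  dir.create(tmp)
  rgb <- array(0, dim = c(16, 16, 3))
  rgb[, , 1] <- 1 # pure red
  png::writePNG(rgb, file.path(tmp, "f0.png"))
  seq <- load_sequence(tmp, target_size = 224)
  expect_equal(seq$native_frames[[1]][1, 1], 0.299 * 255, tolerance = 0.5)
  unlink(tmp, recursive = TRUE)
})

test_that("load_manifest validates schema, labels and splits", {
  base <- tempfile("data")
  dir.create(base)
  seq_dir <- file.path(base, "seqA")
  write_test_sequence(seq_dir, list(matrix(10, 16, 16)))
  path <- file.path(base, "manifest.csv")

  writeLines(c(
    "sequence_directory,label,split",
    "seqA,Benign,train",
    "seqA,MALIGNANT,test"
  ), path)
  mf <- load_manifest(path)
  expect_equal(nrow(mf), 2L)
  expect_equal(mf$label, c("benign", "malignant")) # case-normalized
  expect_equal(mf$split, c("train", "test"))

  writeLines(c("sequence_directory,split", "seqA,train"), path)
  expect_error(load_manifest(path), "missing column")

  writeLines(c("sequence_directory,label,split", "seqA,cystic,train"), path)
  expect_error(load_manifest(path), "unknown label")

  writeLines(c("sequence_directory,label,split", "missing_dir,benign,train"), path)
  expect_error(load_manifest(path), "missing directory")
  unlink(base, recursive = TRUE)
})

test_that("results round-trip through JSON at full precision", {
  set.seed(5)
  frames <- replicate(3, random_speckle_frame(16), simplify = FALSE)
  seq <- bus_sequence(frames, sequence_id = "rt", label = "malignant")
  res <- score_sequence(seq, function(f) runif(1, 0.4, 0.6))
  path <- tempfile(fileext = ".json")
  write_result(res, path)
  back <- read_result(path)
  expect_identical(back$pooled_score, res$pooled_score) # bit-exact
  expect_equal(nrow(back$frames), 3L)
  expect_equal(back$frames$score, res$frames$score)
  expect_equal(back$predicted_label, res$predicted_label)
  expect_equal(back$n_quality, res$n_quality)
  unlink(path)
})

test_that("the N_q = 0 fallback is recorded in the JSON document", {
  frames <- list(matrix(250, 16, 16), matrix(251, 16, 16))
  seq <- bus_sequence(frames, sequence_id = "dark")
  res <- score_sequence(seq, function(f) 0.6)
  path <- tempfile(fileext = ".json")
  write_result(res, path)
  doc <- jsonlite::read_json(path)
  expect_true(doc$summary$low_confidence)
  expect_equal(doc$summary$n_quality, 0L)
  unlink(path)
})

test_that("frames and sequences enforce their invariants", {
  expect_error(bus_frame(matrix(0, 4, 4)), "8x8")
  expect_error(bus_frame(matrix(-1, 8, 8)), "\\[0, 255\\]")
  expect_error(bus_frame(matrix(300, 8, 8)), "\\[0, 255\\]")
  expect_error(bus_sequence(list()), "at least one")
  expect_error(
    bus_sequence(list(matrix(0, 8, 8), matrix(0, 9, 9))),
    "same dimensions"
  )
  expect_error(
    bus_sequence(list(matrix(0, 8, 8)), label = "weird"),
    "unknown label"
  )
})
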