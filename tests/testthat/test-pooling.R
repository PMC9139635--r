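# Quality-gated score pooling and the decision rule.

test_that("pool_malignancy matches hand computations", {
  expect_equal(as.numeric(pool_malignancy(c(0.5, 0.5, 0.5), c(1, 1, 1))), 0.5)
  expect_equal(as.numeric(pool_malignancy(c(0.2, 0.9, 0.4), c(1, 0, 1))), 0.3)
  expect_equal(as.numeric(pool_malignancy(c(0.9), c(1))), 0.9)
})

test_that("pool_malignancy equals the brute-force gated mean on random inputs", {
  set.seed(515)
  for (rep in 1:1000) {
    n <- sample(1:20, 1)
    scores <- runif(n)
    gates <- rbinom(n, 1, 0.6)
    expect_equal(as.numeric(pool_malignancy(scores, gates)),
      oracle_pool(scores, gates),
      tolerance = 1e-12
    )
  }
})

test_that("all-gated-out pooling falls back to the plain mean and flags it", {
  p <- pool_malignancy(c(0.2, 0.6, 0.7), c(0, 0, 0))
  expect_equal(as.numeric(p), mean(c(0.2, 0.6, 0.7)))
  expect_true(attr(p, "fallback"))
  p2 <- pool_malignancy(c(0.2, 0.6), c(1, 0))
  expect_false(attr(p2, "fallback"))
})

test_that("pooling validates its inputs", {
  expect_error(pool_malignancy(numeric(0), numeric(0)), "empty")
  expect_error(pool_malignancy(c(0.5), c(1, 0)), "equal length")
  expect_error(pool_malignancy(c(1.5), c(1)), "\\[0, 1\\]")
  expect_error(pool_malignancy(c(0.5), c(2)), "binary")
})

test_that("pooling is permutation invariant and ignores gated-out frames", {
  set.seed(616)
  for (rep in 1:50) {
    n <- sample(2:15, 1)
    scores <- runif(n)
    gates <- rbinom(n, 1, 0.7)
    if (sum(gates) == 0) gates[1] <- 1
    perm <- sample(n)
    expect_equal(
      as.numeric(pool_malignancy(scores, gates)),
      as.numeric(pool_malignancy(scores[perm], gates[perm])),
      tolerance = 1e-12
    )
    # appending a gated-out frame changes nothing
    expect_equal(
      as.numeric(pool_malignancy(c(scores, 0.99), c(gates, 0))),
      as.numeric(pool_malignancy(scores, gates)),
      tolerance = 1e-12
    )
  }
})

test_that("pooled score is monotone in any gated frame's score", {
  scores <- c(0.2, 0.4, 0.8)
  gates <- c(1, 1, 0)
  base <- as.numeric(pool_malignancy(scores, gates))
  bumped <- scores
  bumped[2] <- 0.9
  expect_gt(as.numeric(pool_malignancy(bumped, gates)), base)
})

test_that("the decision threshold is inclusive for malignant", {
  expect_equal(classify_score(0.5, 0.5), "malignant")
  expect_equal(classify_score(0.46, 0.5), "benign")
  expect_equal(classify_score(0.023, 0.5), "benign")
  expect_equal(classify_score(0.0651, 0.5), "benign")
  expect_equal(classify_score(0.85, 0.5), "malignant")
  expect_equal(classify_score(0.3, 0.2), "malignant")
})

test_that("score_sequence wires scores, gates and the threshold together", {
  set.seed(717)
  # 13-frame sequence; frames 2 and 13 (indices 1 and 12) are darkened so
  # the gate drops them, mirroring a benign sequence with two aberrant
  # high-scoring frames
  cfg <- phantom_config()
  frames <- replicate(13, generate_frame(cfg, "benign")$pixels, simplify = FALSE)
  frames[[2]] <- frames[[2]] * 0.2
  frames[[13]] <- frames[[13]] * 0.2
  seq <- bus_sequence(frames, sequence_id = "benign-aberrant", label = "benign")
  dark <- vapply(frames, function(f) mean(f) < 10, logical(1))
  scorer <- function(frame) if (mean(frame) < 10) 0.9 else 0.2
  res <- score_sequence(seq, scorer)
  expect_s3_class(res, "malignancy_result")
  expect_equal(res$n_frames, 13L)
  expect_equal(res$n_quality, sum(res$frames$gate))
  expect_true(all(res$frames$gate[c(2, 13)] == 0))
  expect_lt(res$pooled_score, 0.5)
  expect_equal(res$predicted_label, "benign")
  # ungated mean would have been pulled up by the two aberrant frames
  expect_gt(mean(res$frames$score), res$pooled_score)
})

test_that("score_sequence with all gates passing equals the plain mean", {
  set.seed(818)
  cfg <- phantom_config()
  g <- generate_sequence(cfg, "malignant", n_frames = 6, corrupt_fraction = 0)
  scorer <- function(frame) mean(frame) / 255
  res <- score_sequence(g$sequence, scorer)
  expect_equal(res$n_quality, 6L)
  expect_equal(res$pooled_score, mean(res$frames$score), tolerance = 1e-12)
})

test_that("score_sequence flags the N_q = 0 fallback as low confidence", {
  set.seed(919)
  frames <- replicate(4, matrix(runif(64 * 64, 200, 255), 64, 64), simplify = FALSE)
  seq <- bus_sequence(frames, sequence_id = "all-bright")
  res <- score_sequence(seq, function(f) 0.7)
  expect_equal(res$n_quality, 0L)
  expect_equal(res$pooled_score, 0.7)
  expect_true(res$low_confidence)
})

test_that("score_sequence rejects scorers that leave the unit interval", {
  seq <- bus_sequence(list(matrix(20, 16, 16)), sequence_id = "x")
  expect_error(score_sequence(seq, function(f) 1.2), "\\[0, 1\\]")
})

test_that("tidy and glance summarize a malignancy result", {
  set.seed(21)
  frames <- replicate(3, random_speckle_frame(16), simplify = FALSE)
  seq <- bus_sequence(frames, sequence_id = "s", label = "benign")
  res <- score_sequence(seq, function(f) 0.25)
  td <- tidy(res)
  expect_equal(nrow(td), 3L)
  expect_true(all(c("sequence_id", "index", "score", "brightness", "blurriness", "gate") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$pooled_score, res$pooled_score)
  expect_s3_class(autoplot(res), "ggplot")
})
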