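# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's computational paths: dense
# convolution by explicit summation, O(n^2) pairwise AUC, direct Eq-style
# arithmetic.

# symmetric (edge-including) reflection index for position i (may be out of
# 1..n)
reflect_index <- function(i, n) {
  # period 2n sawtooth over 1..n
  i <- (i - 1L) %% (2L * n)
  ifelse(i < n, i + 1L, 2L * n - i)
}

# dense 2-D convolution with reflective boundary handling
oracle_convolve2d <- function(x, kernel) {
  n <- nrow(x); m <- ncol(x)
  kr <- (nrow(kernel) - 1L) / 2L
  kc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          ii <- reflect_index(i + a, n)
          jj <- reflect_index(j + b, m)
          s <- s + x[ii, jj] * kernel[a + kr + 1L, b + kc + 1L]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

oracle_gaussian_kernel2d <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- outer(-r:r, -r:r, function(p, q) exp(-(p^2 + q^2) / (2 * sigma^2)))
  g / sum(g)
}

oracle_gaussian_smooth <- function(x, sigma) {
  oracle_convolve2d(x, oracle_gaussian_kernel2d(sigma))
}

oracle_laplacian_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

oracle_blurriness <- function(x, sigma) {
  lap <- oracle_convolve2d(oracle_gaussian_smooth(x, sigma), oracle_laplacian_kernel)
  mean((lap - mean(lap))^2)
}

# Eq.-5-style pooled score by explicit summation
oracle_pool <- function(scores, gates) {
  nq <- 0
  acc <- 0
  for (i in seq_along(scores)) {
    nq <- nq + gates[i]
    acc <- acc + gates[i] * scores[i]
  }
  if (nq > 0) acc / nq else mean(scores)
}

# O(n^2) pairwise rank AUC with half-credit ties
oracle_auc <- function(scores, truth) {
  pos <- which(truth == "malignant")
  neg <- which(truth == "benign")
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
    }
  }
  total / (length(pos) * length(neg))
}

# small random speckle-like frame on the 0-255 scale
random_speckle_frame <- function(n = 16, mean_level = 40, shape = 1) {
  matrix(
    pmin(mean_level * rgamma(n * n, shape, rate = shape), 255), n, n
  )
}

# tiny convnext config used across tests (fast to build and run)
test_net_config <- function(...) {
  convnext_config(
    stage_depths = c(1L, 1L, 1L, 1L), stage_widths = c(4L, 6L, 8L, 10L),
    input_size = 32L, ...
  )
}
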