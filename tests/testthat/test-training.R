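# Training: cross-entropy, augmentation stack, dataset assembly, and the
# seeded Adam loop.

test_that("cross_entropy matches closed forms and is monotone", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-6)
  expect_equal(cross_entropy(c(0, 1), c(0.25, 0.75)), -log(0.75), tolerance = 1e-12)
  # strictly decreasing in the true-class probability
  ps <- seq(0.1, 0.9, by = 0.1)
  losses <- vapply(ps, function(p) cross_entropy(c(1, 0), c(p, 1 - p)), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(cross_entropy(c(1, 0, 0), c(0.5, 0.5)), "length")
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.3)), "sum to 1")
})

test_that("augmentation is a no-op when all probabilities are zero", {
  cfg <- augment_config(
    hflip_prob = 0, rot90_prob = 0, scale_fraction = 0,
    per_op_prob = 0
  )
  set.seed(1)
  f <- random_speckle_frame(32)
  expect_identical(augment_frame(f, cfg), f)
})

test_that("horizontal flip is an involution", {
  f <- matrix(as.numeric(0:255), 16, 16)
  flipped <- f[, 16:1]
  expect_identical(flipped[, 16:1], f)
  # and the augmentation applies exactly that flip when forced
  cfg <- augment_config(hflip_prob = 1, rot90_prob = 0, scale_fraction = 0, per_op_prob = 0)
  set.seed(2)
  expect_identical(augment_frame(f, cfg), flipped)
})

test_that("augmentation is deterministic under a fixed seed and preserves invariants", {
  cfg <- augment_config()
  f <- random_speckle_frame(32, mean_level = 100)
  set.seed(77)
  a1 <- augment_frame(f, cfg)
  set.seed(77)
  a2 <- augment_frame(f, cfg)
  expect_identical(a1, a2)
  set.seed(78)
  for (rep in 1:10) {
    a <- augment_frame(f, cfg)
    expect_equal(dim(a), dim(f))
    expect_true(all(a >= 0 & a <= 255))
  }
})

test_that("collect_frames flattens labelled sequences", {
  set.seed(3)
  cfg <- phantom_config()
  s1 <- generate_sequence(cfg, "benign", 3)$sequence
  s2 <- generate_sequence(cfg, "malignant", 2)$sequence
  set <- collect_frames(list(s1, s2))
  expect_equal(length(set$frames), 5L)
  expect_equal(set$labels, c(rep("benign", 3), rep("malignant", 2)))
  s3 <- bus_sequence(list(matrix(1, 16, 16)), sequence_id = "nolabel")
  expect_error(collect_frames(list(s3)), "no label")
})

make_toy_sets <- function(n_per_class = 6, seed = 5) {
  set.seed(seed)
  mk <- function(level) {
    matrix(pmin(pmax(rnorm(32 * 32, level, 15), 0), 255), 32, 32)
  }
  list(
    frames = c(
      replicate(n_per_class, mk(60), simplify = FALSE),
      replicate(n_per_class, mk(190), simplify = FALSE)
    ),
    labels = rep(c("benign", "malignant"), each = n_per_class)
  )
}

test_that("training reduces the loss and is reproducible under a fixed seed", {
  train_set <- make_toy_sets(6, seed = 5)
  val_set <- make_toy_sets(3, seed = 6)
  model <- build_convnext(test_net_config(), seed = 1)
  tc <- train_config(epochs = 4L, input_size = 32L, seed = 11, augment = NULL)
  fit1 <- train_convnext(model, train_set, val_set, tc)
  expect_s3_class(fit1, "convnext_fit")
  expect_equal(nrow(fit1$history), 4L)
  expect_lt(fit1$history$train_loss[4], fit1$history$train_loss[1])

  fit2 <- train_convnext(model, train_set, val_set, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  gl <- glance(fit1)
  expect_equal(gl$epochs, 4L)
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_s3_class(autoplot(fit1), "ggplot")
})

test_that("a zero learning rate leaves the weights untouched", {
  train_set <- make_toy_sets(2, seed = 7)
  model <- build_convnext(test_net_config(), seed = 2)
  tc <- train_config(
    learning_rate = 0, epochs = 2L, input_size = 32L, seed = 3,
    augment = NULL
  )
  fit <- train_convnext(model, train_set, train_set, tc)
  expect_identical(fit$final_model$params, model$params)
  expect_equal(diff(fit$history$train_loss), 0, tolerance = 1e-12)
})

test_that("training validates inputs and config", {
  model <- build_convnext(test_net_config(), seed = 1)
  empty <- list(frames = list(), labels = character(0))
  ok <- make_toy_sets(2)
  tc <- train_config(epochs = 1L, input_size = 32L)
  expect_error(train_convnext(model, empty, ok, tc), "non-empty")
  tc64 <- train_config(epochs = 1L, input_size = 64L)
  expect_error(train_convnext(model, ok, ok, tc64), "input_size")
  expect_error(train_config(beta1 = 1.2), "beta1")
  expect_error(augment_config(median_kernel = 4), "odd")
})

test_that("training with permuted labels stays near chance on the val split", {
  # leakage guard: randomly relabelled data must not be learnable
  set.seed(13)
  cfg <- phantom_config()
  study <- generate_phantom_study(4, 4, 4, 0, cfg, seed = 13)
  train_set <- collect_frames(study$sequence[study$split != "test"])
  test_set <- collect_frames(study$sequence[study$split == "test"])
  train_set$labels <- sample(train_set$labels)
  model <- build_convnext(convnext_tiny_test_config(), seed = 13)
  tc <- train_config(epochs = 2L, input_size = 64L, seed = 13, augment = NULL)
  fit <- train_convnext(model, train_set, test_set, tc)
  acc <- frame_accuracy(fit$final_model, test_set)
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.8)
})
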