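test_that("the split reproduces the canonical 4812/1926/2888 partition of 9626 beats", {
  labels <- rep(c("low", "high"), each = 4813L)
  sp <- make_split(labels, seed = 1L, repeat_index = 1L)
  expect_identical(length(sp$train), 4812L)
  expect_identical(length(sp$validation), 1926L)
  expect_identical(length(sp$test), 2888L)
  # stratification: exactly half of each partition per class
  expect_identical(as.integer(table(labels[sp$test])), c(1444L, 1444L))
  expect_identical(as.integer(table(labels[sp$validation])), c(963L, 963L))
})

test_that("splits are disjoint, exhaustive, stratified within one sample, and seeded", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    labels <- sample(c("low", "high"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (min(table(labels)) < 3) next
    sp <- make_split(labels, seed = i, repeat_index = 2L)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_identical(sort(all_idx), seq_len(n))
    expect_identical(length(sp$test), as.integer(ceiling(0.3 * n)))
    expect_identical(length(sp$validation),
                     as.integer(ceiling(2 / 7 * (n - length(sp$test)))))
    # class proportions preserved within one sample per partition
    p_high <- mean(labels == "high")
    for (part in sp) {
      expect_lte(abs(sum(labels[part] == "high") - p_high * length(part)), 1)
    }
  }
  labels <- rep(c("low", "high"), each = 50)
  expect_identical(make_split(labels, seed = 4L, repeat_index = 3L),
                   make_split(labels, seed = 4L, repeat_index = 3L))
  expect_false(identical(make_split(labels, seed = 4L, repeat_index = 3L),
                         make_split(labels, seed = 4L, repeat_index = 4L)))
})

test_that("a 10-sample balanced split gives sizes (5, 2, 3) with both classes everywhere", {
  labels <- rep(c("a", "b"), each = 5)
  sp <- make_split(labels, seed = 2L)
  expect_identical(lengths(sp), c(train = 5L, validation = 2L, test = 3L))
  for (part in sp) expect_identical(length(unique(labels[part])), 2L)
  expect_error(make_split(c("a", "a", "b")), "fewer than 3")
})

test_that("accuracy is the diagonal fraction and rejects empty matrices", {
  expect_identical(accuracy(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_identical(accuracy(matrix(c(5, 5, 5, 5), 2)), 0.5)
  expect_error(accuracy(matrix(0, 2, 2)), "zero total")
  # error rate of a pooled matrix: 2054 misclassifications in a 14,440
  # pooled total is an overall accuracy near 78% (plausibility of the
  # pooling arithmetic, nothing model-specific)
  cm <- matrix(c(5500, 2054, 1110, 5776), 2)
  expect_equal(accuracy(cm), (5500 + 5776) / 14440)
})

test_that("the model comparison t-test matches the closed-form pooled computation", {
  res <- compare_models(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  # closed form: pooled var = 0.01, se = 0.1 * sqrt(2/3), df = 4
  t_exp <- (0.2 - 0.5) / (0.1 * sqrt(2 / 3))
  expect_equal(res$t_statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$t_statistic, -3.674, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * pt(t_exp, df = 4), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)
  expect_identical(res$df, 4)
  # symmetry and the identical-group convention
  swap <- compare_models(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(swap$t_statistic, -res$t_statistic)
  expect_equal(swap$p_value, res$p_value)
  same <- compare_models(rep(0.8, 5), rep(0.8, 5))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
})

test_that("train_and_evaluate pools confusion matrices over repeats and logs choices", {
  set.seed(62)
  dat <- make_bright_dark_series(80L, 32L, seed = 406L)
  cfg <- experiment_config(optimizers = "adam", learning_rates = c(0.01, 0.001),
                           batch_size = 16L, epochs = 4L, n_repeats = 3L,
                           seed = 5L)
  res <- train_and_evaluate(dat$x, dat$y, "FCN1D", cfg, method = "raw")
  expect_s3_class(res, "bcg_experiment_result")
  expect_length(res$per_repeat_accuracy, 3L)
  expect_equal(res$mean_accuracy, mean(res$per_repeat_accuracy))
  expect_equal(res$sd_accuracy, sd(res$per_repeat_accuracy))
  n_test <- length(make_split(dat$y, seed = 5L, repeat_index = 1L)$test)
  expect_identical(sum(res$pooled_confusion), 3L * n_test)
  expect_length(res$hyperparams, 3L)
  expect_true(all(vapply(res$hyperparams, function(h)
    h$lr %in% c(0.01, 0.001), logical(1))))
  expect_error(
    train_and_evaluate(dat$x, dat$y, "FCN1D",
                       experiment_config(optimizers = character(0))),
    "optimizers")
})
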