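test_that("model_config validates its fields", {
  expect_error(model_config(channels = c(8, 0, 8, 8, 8)),
               class = "ihrc_config_error")
  expect_error(model_config(threshold = 1.2), class = "ihrc_config_error")
  expect_error(model_config(kernel = 5), class = "ihrc_config_error")
  expect_error(model_config(optimizer = "sgd"), class = "ihrc_config_error")
  cfg <- model_config()
  expect_equal(cfg$channels, c(512L, 1024L, 512L, 1024L, 1024L))
  expect_equal(cfg$input_length, 31L)
})

test_that("builds are seeded and deterministic", {
  cfg <- tiny_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(seed = 12L))
  expect_false(identical(m1$params, m3$params))
})

test_that("prediction respects the I/O contract", {
  m <- build_model(tiny_config())
  expect_error(predict(m, matrix(0, 2, 30)), class = "ihrc_shape_error")
  empty <- predict(m, matrix(numeric(), 0, 31))
  expect_equal(nrow(empty), 0L)
  p <- predict(m, matrix(rnorm(31 * 7), 7, 31))
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  # label flips when the threshold crosses the probability
  x1 <- matrix(rnorm(31 * 7), 7, 31)
  p_lo <- predict(m, x1, threshold = 1e-6)
  p_hi <- predict(m, x1, threshold = 1 - 1e-6)
  expect_true(all(p_lo$label == 1L))
  expect_true(all(p_hi$label == 0L))
})

separable_toy <- function(n = 50, seed = 23) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * 31, sd = 0.3), n, 31)
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)
  list(x = x, y = y)
}

test_that("a separable toy set is fit to training accuracy 1", {
  toy <- separable_toy()
  cfg <- tiny_config(epochs = 200L)
  m <- train_model(build_model(cfg), toy$x, toy$y)
  pred <- predict(m, toy$x)
  expect_equal(mean(pred$label == toy$y), 1.0)
  expect_equal(nrow(m$log), 200L)
})

test_that("training is reproducible and validates inputs", {
  toy <- separable_toy(30)
  cfg <- tiny_config(epochs = 5L)
  m1 <- train_model(build_model(cfg), toy$x, toy$y)
  m2 <- train_model(build_model(cfg), toy$x, toy$y)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params, m2$params)
  expect_error(train_model(build_model(cfg), toy$x, rep(1L, 30)),
               class = "ihrc_training_error")
  expect_error(train_model(build_model(cfg), toy$x, toy$y[-1]),
               class = "ihrc_contract_error")
})

test_that("prediction is invariant to batch partitioning", {
  toy <- separable_toy(70)
  m <- train_model(build_model(tiny_config(epochs = 3L)), toy$x, toy$y)
  p_one <- predict(m, toy$x)
  m$config$batch_size <- 7L
  p_small <- predict(m, toy$x)
  expect_equal(p_one$probability, p_small$probability, tolerance = 1e-10)
})

test_that("metrics match hand-computed confusion matrices", {
  perfect <- evaluate_predictions(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)

  even <- evaluate_predictions(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(c(even$TP, even$FP, even$TN, even$FN), c(1L, 1L, 1L, 1L))
  expect_equal(even$ACC, 0.5)
  expect_equal(even$MCC, 0)

  m <- evaluate_predictions(c(1, 1, 1, 0, 0, 0, 0), c(1, 1, 0, 1, 0, 0, 0))
  expect_equal(c(m$TP, m$FP, m$TN, m$FN), c(2L, 1L, 3L, 1L))
  expect_equal(m$ACC, 5 / 7)
  expect_equal(m$MCC, 5 / 12)
})

test_that("degenerate confusion matrices report 0 with a flag", {
  allneg <- evaluate_predictions(rep(0, 6), c(1, 0, 1, 0, 0, 0))
  expect_equal(allneg$MCC, 0)
  expect_true(all(c("Precision", "MCC") %in% allneg$undefined))
  expect_error(evaluate_predictions(c(1, 0), c(1, 0, 0)),
               class = "ihrc_contract_error")
  expect_error(evaluate_predictions(c(2, 0), c(1, 0)),
               class = "ihrc_contract_error")
})

test_that("metrics agree with the brute-force oracle on random vectors", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pred <- rbinom(n, 1, 0.4)
    truth <- rbinom(n, 1, 0.3)
    m <- evaluate_predictions(pred, truth)
    o <- metrics_oracle(pred, truth)
    expect_equal(m$ACC, o$ACC)
    expect_equal(m$Precision, o$Precision)
    expect_equal(m$Recall, o$Recall)
    expect_equal(m$MCC, o$MCC, tolerance = 1e-12)
  }
})

test_that("kfold_split partitions proteins with near-equal folds", {
  ids <- sprintf("P%02d", 1:10)
  folds <- kfold_split(ids, k = 5, seed = 3)
  expect_length(folds, 5L)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(test_sets) == 2L))
  expect_setequal(unlist(test_sets), ids)
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(folds, kfold_split(ids, k = 5, seed = 3))
  # uneven division: fold sizes differ by at most one
  f7 <- kfold_split(sprintf("Q%d", 1:7), k = 3, seed = 1)
  expect_true(diff(range(lengths(lapply(f7, `[[`, "test")))) <= 1L)
  expect_error(kfold_split(ids[1:3], k = 5), class = "ihrc_config_error")
})

test_that("checkpoints round-trip through the text format", {
  toy <- separable_toy(20)
  m <- train_model(build_model(tiny_config(epochs = 2L)), toy$x, toy$y)
  f <- withr::local_tempfile(fileext = ".txt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, toy$x), predict(m, toy$x), tolerance = 1e-12)
  expect_equal(m2$config$channels, m$config$channels)
  expect_true(m2$trained)
})
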