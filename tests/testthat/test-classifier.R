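test_that("metric identities hold for the worked confusion matrix", {
  m <- eval_metrics(tp = 45, fp = 5, fn = 3, tn = 47)
  expect_equal(m$precision, 0.900)
  expect_equal(m$recall, 0.9375)
  expect_equal(m$f1, 0.9183673, tolerance = 1e-6)
  expect_equal(m$accuracy, 0.92)
  expect_false(m$degenerate)
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(0:50, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    m <- eval_metrics(k[1], k[2], k[3], k[4])
    expect_equal(m$accuracy, (k[1] + k[4]) / sum(k))
    if (k[1] + k[2] > 0) expect_equal(m$precision, k[1] / (k[1] + k[2]))
    if (k[1] + k[3] > 0) expect_equal(m$recall, k[1] / (k[1] + k[3]))
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                               "f1")]) >= 0))
  }
  deg <- eval_metrics(0, 0, 0, 10)   # no positives predicted or present
  expect_true(deg$degenerate)
  expect_equal(deg$f1, 0)
  expect_error(eval_metrics(-1, 0, 0, 1), "non-negative")
  expect_error(eval_metrics(0, 0, 0, 0), "empty")
})

test_that("a published precision/recall pair implies its f1", {
  # precision 0.90, recall 0.94 -> harmonic mean ~ 0.92
  expect_equal(2 * 0.90 * 0.94 / (0.90 + 0.94), 0.9195652,
               tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  ds <- small_dataset(seed = 2)
  a <- fit_window_classifier(ds, seed = 7,
                             architecture = window_cnn(epochs = 60))
  b <- fit_window_classifier(ds, seed = 7,
                             architecture = window_cnn(epochs = 60))
  expect_identical(predict(a, ds, type = "prob"),
                   predict(b, ds, type = "prob"))
})

test_that("training reaches perfect accuracy on noiseless data", {
  models <- lapply(exercise_catalog()[1:2], exercise_signal_model,
                   noise_sd = 0)
  ds <- build_dataset(models, n_per_class = 3, duration_seconds = 6,
                      seed = 1)
  clf <- fit_window_classifier(ds, seed = 1)
  expect_equal(evaluate(clf, ds, part = "train")$accuracy, 1)
})

test_that("the trained classifier beats the majority-class baseline", {
  ds <- small_dataset(seed = 1, n_per_class = 5)
  clf <- fit_window_classifier(ds, seed = 1)
  test <- dataset_part(ds, "test")
  baseline <- max(table(test$y)) / length(test$y)
  expect_gt(evaluate(clf, ds)$accuracy, baseline)
})

test_that("training rejects degenerate inputs", {
  ds <- small_dataset(seed = 1)
  one_class <- ds
  keep <- ds$y == "correct"
  one_class$x <- ds$x[keep, , , drop = FALSE]
  one_class$y <- ds$y[keep]
  one_class$exercise <- ds$exercise[keep]
  one_class$split <- ds$split[keep]
  expect_error(fit_window_classifier(one_class, seed = 1),
               "both correctness classes")
  clf <- fit_window_classifier(ds, seed = 1,
                               architecture = window_cnn(epochs = 30))
  short <- array(0, c(2, 30, 8),
                 dimnames = list(NULL, NULL, dimnames(ds$x)[[3]]))
  expect_error(predict(clf, short), "expects")
})

test_that("masked channels cannot influence predictions", {
  ds <- small_dataset(seed = 4)
  clf <- fit_window_classifier(ds, channels = "no_IMU", seed = 1,
                               architecture = window_cnn(epochs = 60))
  perturbed <- ds
  set.seed(99)
  imu <- c("ax", "ay", "az", "gx", "gy", "gz")
  perturbed$x[, , imu] <- perturbed$x[, , imu] +
    array(rnorm(length(perturbed$x[, , imu]), 0, 50), dim = c(dim(ds$x)[1:2], 6))
  expect_identical(predict(clf, ds, type = "prob"),
                   predict(clf, perturbed, type = "prob"))
})

test_that("the ablation harness reports one row per channel group", {
  ds <- small_dataset(seed = 5)
  ab <- ablation_study(ds, seed = 1,
                       architecture = window_cnn(epochs = 60))
  expect_equal(ab$group, c("full", "no_IMU", "no_flex"))
  expect_equal(ab$n_channels, c(8L, 2L, 6L))
  expect_equal(ab$delta_accuracy,
               ab$accuracy - ab$accuracy[ab$group == "full"])
  expect_error(ablation_study(ds, channel_groups = "no_gyro", seed = 1),
               "unknown channel")
})

test_that("a checkpoint round-trip preserves predictions", {
  ds <- small_dataset(seed = 6)
  clf <- fit_window_classifier(ds, seed = 2,
                               architecture = window_cnn(epochs = 40))
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, f)
  clf2 <- load_classifier(f)
  expect_equal(predict(clf2, ds, type = "prob"),
               predict(clf, ds, type = "prob"), tolerance = 1e-12)
  expect_identical(clf2$channels, clf$channels)
})
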