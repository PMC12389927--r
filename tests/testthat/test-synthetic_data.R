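test_that("stream simulation is seeded and deterministic", {
  m <- exercise_signal_model("fist_open_close")
  a <- simulate_exercise_stream(m, "correct", 10, seed = 4)
  b <- simulate_exercise_stream(m, "correct", 10, seed = 4)
  expect_identical(a, b)
  c <- simulate_exercise_stream(m, "incorrect", 10, seed = 4)
  d <- simulate_exercise_stream(m, "incorrect", 10, seed = 5)
  expect_identical(c, simulate_exercise_stream(m, "incorrect", 10, seed = 4))
  expect_false(identical(c$data, d$data))
})

test_that("10 s at 21 Hz yields 210 samples and labels are attached", {
  m <- exercise_signal_model("finger_spread")
  s <- simulate_exercise_stream(m, "incorrect", 10, seed = 1)
  expect_equal(nrow(s$data), 210L)
  expect_identical(s$exercise_label, "finger_spread")
  expect_identical(s$correctness_label, "incorrect")
  expect_error(simulate_exercise_stream(m, "correct", 1.5, seed = 1),
               "at least one")
})

test_that("a zero-noise correct stream is the template, seed-independent", {
  m <- exercise_signal_model("wrist_flexion_extension", noise_sd = 0)
  a <- simulate_exercise_stream(m, "correct", 4, seed = 1)
  b <- simulate_exercise_stream(m, "correct", 4, seed = 999)
  expect_identical(a$data, b$data)
  # noise perturbs it
  mn <- exercise_signal_model("wrist_flexion_extension", noise_sd = 0.35)
  expect_false(identical(
    simulate_exercise_stream(mn, "correct", 4, seed = 1)$data, a$data))
})

test_that("generated ADC counts respect the 12-bit range", {
  m <- exercise_signal_model("fist_open_close", noise_sd = 2)  # violent noise
  s <- simulate_exercise_stream(m, "correct", 20, seed = 2)
  for (ch in c("flex_middle", "flex_thumb")) {
    expect_true(all(s$data[[ch]] >= 0 & s$data[[ch]] <= 4095))
    expect_true(is.integer(s$data[[ch]]))
  }
})

test_that("dataset construction is balanced, stratified and seeded", {
  ds <- small_dataset(seed = 3, n_per_class = 5)
  # uniform class histogram by construction
  expect_equal(length(unique(table(ds$exercise, ds$y))), 1L)
  # stratified split: per-class train counts within 1 window of the target
  for (cls in unique(paste(ds$exercise, ds$y))) {
    idx <- paste(ds$exercise, ds$y) == cls
    expect_lte(abs(sum(ds$split[idx] == "train") - 0.7 * sum(idx)), 1)
  }
  ds2 <- small_dataset(seed = 3, n_per_class = 5)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$x, ds2$x)
  expect_error(build_dataset(list(exercise_signal_model("fist_open_close")),
                             n_per_class = 4), "2 exercise classes")
  expect_error(small_dataset(n_per_class = 1), "at least 2")
})

test_that("cohort simulation matches its target summaries", {
  co <- simulate_cohort(cohort_spec(), seed = 3)
  expect_identical(co, simulate_cohort(cohort_spec(), seed = 3))
  expect_equal(nrow(co), 6L * 8L)
  s <- summarize_cohort(co)
  tgt <- trial_summary()
  for (i in seq_len(nrow(tgt))) {
    row <- s[s$scale == tgt$scale[i] & s$group == as.character(tgt$group[i]), ]
    tol <- if (tgt$scale[i] == "FIM") 0.05 else 1e-10  # FIM is discretized
    expect_equal(row$mean_change, tgt$mean_change[i], tolerance = tol,
                 ignore_attr = TRUE)
    expect_equal(row$sd_change, tgt$sd_change[i], tolerance = tol,
                 ignore_attr = TRUE)
  }
})

test_that("cohort parameter recovery holds within 1% at n = 10^4", {
  spec <- cohort_spec(transform(trial_summary(), n = 10000L))
  s <- summarize_cohort(simulate_cohort(spec, seed = 17))
  tgt <- trial_summary()
  for (i in seq_len(nrow(tgt))) {
    row <- s[s$scale == tgt$scale[i] & s$group == as.character(tgt$group[i]), ]
    expect_lt(abs(row$mean_change - tgt$mean_change[i]) /
                abs(tgt$mean_change[i]), 0.01)
    expect_lt(abs(row$sd_change - tgt$sd_change[i]) / tgt$sd_change[i],
              0.01)
  }
})

test_that("cohort values respect scale ranges and clipping is logged", {
  spec <- cohort_spec(transform(trial_summary(), n = 2000L))
  co <- simulate_cohort(spec, seed = 5)
  rng <- list("MORE" = c(17, 85), "FIM" = c(18, 126), "FMA-UE" = c(0, 66))
  for (sc in names(rng)) {
    v <- unlist(co[co$scale == sc, c("week1", "week2", "week3")])
    expect_true(all(v >= rng[[sc]][1] & v <= rng[[sc]][2]))
  }
  expect_true(all(co$week3[co$scale == "FIM"] ==
                    round(co$week3[co$scale == "FIM"])))
  clip <- attr(co, "clipping")
  expect_s3_class(clip, "data.frame")
  expect_true(all(clip$clamped >= 0))
})

test_that("degenerate and invalid cohort specifications are handled", {
  summ <- trial_summary()
  summ$sd_change[1] <- 0
  co <- simulate_cohort(cohort_spec(summ), seed = 1)
  ch <- co$week3 - co$week1
  cell <- co$scale == summ$scale[1] &
    co$group == as.character(summ$group[1])
  expect_true(all(ch[cell] == summ$mean_change[1]))
  summ$sd_change[1] <- -1
  expect_error(cohort_spec(summ), "non-negative")
  summ2 <- trial_summary(); summ2$n[2] <- 1
  expect_error(cohort_spec(summ2), ">= 2")
})
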