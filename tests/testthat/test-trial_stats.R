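# Expected p-values below were frozen from an independent oracle
# (numerical integration of the t density in helper-oracles.R) or from
# full enumeration for the rank tests; published table values are asserted
# at their printed precision in test-acceptance.R.

test_that("paired t from a summary triple matches the known example", {
  r <- paired_t_from_summary(group_summary("FMA-UE", "experimental",
                                           8, 9.38, 9.90))
  expect_equal(abs(r$statistic), 2.68, tolerance = 0.005)
  expect_equal(r$df, 7)
  expect_equal(r$p_value, 0.0316, tolerance = 0.002 / 0.0316)
  expect_equal(r$effect_size_d, 0.95, tolerance = 0.005)
  # null case
  r0 <- paired_t_from_summary(group_summary("x", "g", 10, 0, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$effect_size_d, 0)
  expect_error(paired_t_from_summary(group_summary("x", "g", 1, 1, 1)),
               ">= 2")
})

test_that("paired t on raw deltas (1,2,3) matches the integration oracle", {
  r <- paired_t_from_raw(c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, p_from_t_integration(2 * sqrt(3), 2),
               tolerance = 1e-6)   # 0.0741799
})

test_that("summary and raw paired-t paths agree to machine precision", {
  set.seed(11)
  for (i in 1:25) {
    z <- rnorm(sample(3:30, 1), sample(-3:3, 1), runif(1, 0.5, 5))
    a <- paired_t_from_raw(z)
    b <- paired_t_from_summary(summary_from_changes(z))
    expect_identical(a, b)
    tt <- t.test(z)   # independent route
    expect_equal(a$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("Student's t between groups matches hand arithmetic", {
  r <- student_t_between(group_summary("x", "a", 2, 1.0, 1.0),
                         group_summary("x", "b", 2, 0.0, 1.0))
  expect_equal(r$statistic, 1.0)
  expect_equal(r$df, 2)
  expect_equal(r$effect_size_d, 1.0)
  sym <- student_t_between(group_summary("x", "a", 8, 2.5, 3),
                           group_summary("x", "b", 8, 2.5, 3))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$effect_size_d, 0)
})

test_that("Welch-Satterthwaite df matches direct evaluation", {
  r <- welch_t_between(group_summary("x", "a", 8, 1, 1),
                       group_summary("x", "b", 8, 0, 2))
  expect_equal(r$df, 0.625^2 / ((0.125^2 + 0.5^2) / 7), tolerance = 1e-12)
  expect_equal(r$df, 10.29412, tolerance = 1e-6)
})

test_that("Welch reduces exactly to Student under equal variances and n", {
  a <- group_summary("x", "a", 9, 4.2, 2.5)
  b <- group_summary("x", "b", 9, 1.1, 2.5)
  w <- welch_t_between(a, b)
  s <- student_t_between(a, b)
  expect_equal(w$statistic, s$statistic, tolerance = 1e-14)
  expect_equal(w$df, s$df, tolerance = 1e-14)
  expect_equal(w$p_value, s$p_value, tolerance = 1e-14)
  # and against R's own implementations on matching raw data
  set.seed(21)
  x <- rnorm(8, 1, 2); y <- rnorm(8, 0, 5)
  ws <- welch_t_between(summary_from_changes(x), summary_from_changes(y))
  tw <- t.test(x, y)
  expect_equal(ws$statistic, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(ws$df, unname(tw$parameter), tolerance = 1e-9)
  expect_equal(ws$p_value, tw$p.value, tolerance = 1e-12)
})

test_that("assumption checks behave under null and violated variances", {
  set.seed(31)
  null_flags <- replicate(20, {
    a <- rnorm(50); b <- rnorm(50) + 2   # shifted, same variance
    assumption_checks(a, b)$equal_variance_ok
  })
  expect_gt(mean(null_flags), 0.8)
  rejected <- replicate(200, {
    a <- rnorm(50); b <- rnorm(50) * 10
    !assumption_checks(a, b)$equal_variance_ok
  })
  expect_gte(mean(rejected), 0.95)
  # heavily discretized small sample still yields a valid Shapiro-Wilk p
  ck <- assumption_checks(c(1, 1, 2, 2, 2, 3, 3, 9),
                          c(0, 0, 1, 1, 1, 2, 2, 2))
  expect_true(all(ck$shapiro_p > 0 & ck$shapiro_p <= 1))
  expect_error(assumption_checks(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("the between-test selector follows the variance flag", {
  forge <- function(p, alpha = 0.05)
    structure(list(levene_p = p, equal_variance_ok = p >= alpha,
                   alpha = alpha), class = "assumption_checks")
  expect_equal(select_between_test(forge(0.0058)), "welch_t")
  expect_equal(select_between_test(forge(0.519)), "student_t")
  # boundary: p exactly at alpha is not evidence of unequal variances
  expect_equal(select_between_test(forge(0.05)), "student_t")
})

test_that("exact rank-test p-values match full enumeration", {
  np <- nonparametric_checks(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(unname(np$mann_whitney$statistic), 0)
  expect_true(np$mann_whitney$exact)
  expect_equal(np$mann_whitney$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(np$mann_whitney$p_value,
               mann_whitney_exact_p(c(1, 2, 3, 4), c(10, 20, 30, 40)),
               tolerance = 1e-12)
  expect_equal(np$wilcoxon_a$p_value, wilcoxon_exact_p(c(1, 2, 3, 4)),
               tolerance = 1e-12)
  # all-positive deltas (1, 2, 3): 2 of the 2^3 sign patterns are as extreme
  np3 <- nonparametric_checks(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(np3$wilcoxon_a$p_value, 0.25, tolerance = 1e-12)
  expect_equal(wilcoxon_exact_p(c(1, 2, 3)), 0.25, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:10) {
    a <- round(rnorm(sample(4:7, 1), 0, 10), 3)
    b <- round(rnorm(sample(4:7, 1), 1, 10), 3)
    np <- nonparametric_checks(a, b)
    expect_equal(np$mann_whitney$p_value, mann_whitney_exact_p(a, b),
                 tolerance = 1e-12)
    expect_equal(np$wilcoxon_a$p_value, wilcoxon_exact_p(a),
                 tolerance = 1e-12)
    expect_equal(np$wilcoxon_b$p_value, wilcoxon_exact_p(b),
                 tolerance = 1e-12)
  }
})

test_that("rank tests behave under a symmetric null and degenerate input", {
  set.seed(51)
  rejections <- replicate(50, {
    nonparametric_checks(rnorm(8), rnorm(8))$wilcoxon_a$p_value < 0.05
  })
  expect_lte(sum(rejections), 6)
  expect_error(nonparametric_checks(c(0, 0, 0), c(1, 2, 3)), "degenerate")
})

test_that("MCID/MDC annotation applies the published thresholds", {
  a <- annotate_mcid("FMA-UE", 9.38)
  expect_true(a$meets_mcid)
  expect_true(a$exceeds_mdc)
  b <- annotate_mcid("FMA-UE", 5.38)
  expect_false(b$meets_mcid)
  expect_true(b$exceeds_mdc)   # 5.38 > 5.2
  f <- annotate_mcid("FIM", 3.0)
  expect_false(f$meets_mcid)
  expect_true(is.na(f$exceeds_mdc))
  m <- annotate_mcid("MORE", 2.25)
  expect_true(is.na(m$threshold_mcid))
  expect_true(is.na(m$meets_mcid))
  expect_error(annotate_mcid("ARAT", 5), "unknown scale")
})

test_that("the full analysis validates its input structure", {
  expect_error(run_full_analysis(data.frame()), "empty")
  summ <- trial_summary()
  expect_error(run_full_analysis(summ[-3, ]), "missing.*FIM")
  expect_error(run_full_analysis(data.frame(x = 1)), "summary table")
})

test_that("raw-path analysis on a simulated cohort is self-consistent", {
  co <- simulate_cohort(cohort_spec(), seed = 12)
  an <- run_full_analysis(co)
  expect_equal(an$input, "raw")
  expect_equal(nrow(an$within), 6L)
  expect_equal(nrow(an$between), 3L)
  expect_equal(nrow(an$assumptions), 3L)
  expect_equal(nrow(an$nonparametric), 3L)
  # within-group rows agree with direct t-tests on the raw changes
  for (i in seq_len(nrow(an$within))) {
    row <- an$within[i, ]
    ch <- co$week3[co$scale == row$scale & co$group == row$group] -
      co$week1[co$scale == row$scale & co$group == row$group]
    tt <- t.test(ch)
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  }
  # selected method consistent with the Levene flag
  expect_equal(an$between$selected,
               ifelse(an$assumptions$equal_variance_ok, "student_t",
                      "welch_t"))
})
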