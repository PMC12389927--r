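# Feasibility-trial statistics over the MORE, FIM and FMA-UE clinical
# scales: within-group paired t-tests, between-group Student/Welch t-tests
# gated on a variance-equality check, Cohen's d effect sizes, Shapiro-Wilk
# normality checks, non-parametric sensitivity tests, and MCID/MDC
# annotation. Every parametric test is computable from the printed
# (n, mean change, SD change) summary triples alone; the raw-score path
# adds the assumption checks and non-parametric tests that need
# per-patient data. All p-values are two-sided.
#
# Sign convention: t is signed by the change (week3 - week1), so an
# improvement gives a positive statistic; published tables that sign the
# statistic the opposite way agree in magnitude.

#' Per-group change-score summary
#'
#' The unit of the summary-statistics analysis path: sample size, mean
#' change (week 3 minus week 1) and SD of change for one clinical scale in
#' one trial arm.
#'
#' @param scale Scale name (e.g. `"MORE"`, `"FIM"`, `"FMA-UE"`).
#' @param group Group name (e.g. `"experimental"`, `"control"`).
#' @param n Sample size (integer >= 2).
#' @param mean_change Mean change in scale points.
#' @param sd_change SD of change in scale points (> 0).
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' group_summary("FMA-UE", "experimental", 8, 9.38, 9.90)
group_summary <- function(scale, group, n, mean_change, sd_change) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(sd_change) || sd_change <= 0)
    stop("`sd_change` must be positive", call. = FALSE)
  structure(list(scale = scale, group = group, n = as.integer(n),
                 mean_change = mean_change, sd_change = sd_change),
            class = "group_summary")
}

#' Summarize a raw change-score vector
#'
#' @param changes Numeric vector of per-patient change scores.
#' @inheritParams group_summary
#' @return A [group_summary()].
#' @export
summary_from_changes <- function(changes, scale = NA_character_,
                                 group = NA_character_) {
  if (length(changes) < 2L)
    stop("at least 2 change scores are required", call. = FALSE)
  group_summary(scale, group, length(changes), mean(changes), sd(changes))
}

.as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.list(x) && all(c("n", "mean_change", "sd_change") %in% names(x)))
    return(group_summary(if (is.null(x$scale)) NA_character_ else
      as.character(x$scale),
      if (is.null(x$group)) NA_character_ else as.character(x$group),
      x$n, x$mean_change, x$sd_change))
  stop("expected a `group_summary` (or list with n, mean_change, sd_change)",
       call. = FALSE)
}

test_result <- function(statistic, df, p_value, effect_size_d, method,
                        n = NA_integer_, exact = NA) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 effect_size_d = effect_size_d, method = method, n = n,
                 exact = exact),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method, ": statistic ",
      sprintf("%.3f", x$statistic),
      if (is.finite(x$df)) sprintf(", df %.4g", x$df),
      sprintf(", p %.4g", x$p_value),
      if (is.finite(x$effect_size_d))
        sprintf(", d %.2f", x$effect_size_d),
      if (isTRUE(x$exact)) " (exact)", "\n", sep = "")
  invisible(x)
}

#' Within-group paired t-test from a change-score summary
#'
#' `t = mean_change / (sd_change / sqrt(n))` with `n - 1` degrees of
#' freedom and a two-sided p-value; the paired Cohen's d is
#' `mean_change / sd_change`. Applied to the summary of a raw change
#' vector this reproduces the direct paired t-test exactly.
#'
#' @param summary A [group_summary()].
#' @return A `test_result` with method `"paired_t"`.
#' @export
#' @examples
#' paired_t_from_summary(group_summary("FMA-UE", "experimental",
#'                                     8, 9.38, 9.90))
paired_t_from_summary <- function(summary) {
  s <- .as_group_summary(summary)
  t <- s$mean_change / (s$sd_change / sqrt(s$n))
  df <- s$n - 1
  test_result(t, df, 2 * pt(-abs(t), df), s$mean_change / s$sd_change,
              "paired_t", n = s$n)
}

#' Within-group paired t-test from raw change scores
#'
#' @param changes Numeric vector of per-patient change scores (week 3 minus
#'   week 1).
#' @return A `test_result` with method `"paired_t"`.
#' @export
paired_t_from_raw <- function(changes) {
  paired_t_from_summary(summary_from_changes(changes))
}

.pooled_sd <- function(a, b)
  sqrt(((a$n - 1) * a$sd_change^2 + (b$n - 1) * b$sd_change^2) /
         (a$n + b$n - 2))

#' Between-group Student's t-test from summaries
#'
#' Pooled-variance two-sample t-test on change scores with
#' `n1 + n2 - 2` degrees of freedom; Cohen's d uses the pooled SD.
#'
#' @param summary_a,summary_b [group_summary()]s for the two groups
#'   (difference taken as a minus b).
#' @return A `test_result` with method `"student_t"`.
#' @export
#' @examples
#' student_t_between(group_summary("MORE", "experimental", 8, 2.25, 4.10),
#'                   group_summary("MORE", "control", 8, -1.12, 4.94))
student_t_between <- function(summary_a, summary_b) {
  a <- .as_group_summary(summary_a); b <- .as_group_summary(summary_b)
  sp <- .pooled_sd(a, b)
  diff <- a$mean_change - b$mean_change
  t <- diff / (sp * sqrt(1 / a$n + 1 / b$n))
  df <- a$n + b$n - 2
  test_result(t, df, 2 * pt(-abs(t), df), diff / sp, "student_t",
              n = a$n + b$n)
}

#' Between-group Welch's t-test from summaries
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom
#' `(s1^2/n1 + s2^2/n2)^2 / ((s1^2/n1)^2/(n1-1) + (s2^2/n2)^2/(n2-1))`.
#' Cohen's d is reported with the pooled SD (a single d formula per
#' comparison, matching the Student variant). With equal SDs and equal
#' group sizes, statistic, df and p reduce exactly to Student's t.
#'
#' @inheritParams student_t_between
#' @return A `test_result` with method `"welch_t"` (df generally
#'   non-integer).
#' @export
#' @examples
#' welch_t_between(group_summary("FMA-UE", "experimental", 8, 9.38, 9.90),
#'                 group_summary("FMA-UE", "control", 8, 5.38, 22.88))
welch_t_between <- function(summary_a, summary_b) {
  a <- .as_group_summary(summary_a); b <- .as_group_summary(summary_b)
  va <- a$sd_change^2 / a$n; vb <- b$sd_change^2 / b$n
  diff <- a$mean_change - b$mean_change
  t <- diff / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  test_result(t, df, 2 * pt(-abs(t), df), diff / .pooled_sd(a, b),
              "welch_t", n = a$n + b$n)
}

#' Normality and variance-equality checks on raw change scores
#'
#' Shapiro-Wilk per group and Levene's test across groups (classic Levene:
#' absolute deviations from the group mean by default; the Brown-Forsythe
#' median-centred variant is available via `center`). Boolean flags are
#' derived at significance level `alpha`: normality holds when both
#' Shapiro-Wilk p-values exceed `alpha`, variances are treated as equal
#' when Levene's p exceeds or equals `alpha` (a boundary p exactly at
#' `alpha` is not taken as evidence of unequal variances).
#'
#' @param changes_a,changes_b Raw per-patient change-score vectors for the
#'   two groups (each of length >= 3 for Shapiro-Wilk).
#' @param alpha Significance level (default 0.05).
#' @param center `"mean"` (classic Levene, default) or `"median"`.
#' @return An object of class `assumption_checks`.
#' @export
assumption_checks <- function(changes_a, changes_b, alpha = 0.05,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(changes_a) < 3L || length(changes_b) < 3L)
    stop("Shapiro-Wilk requires at least 3 observations per group",
         call. = FALSE)
  sh_a <- shapiro.test(changes_a)$p.value
  sh_b <- shapiro.test(changes_b)$p.value
  y <- c(changes_a, changes_b)
  g <- factor(rep(c("a", "b"), c(length(changes_a), length(changes_b))))
  lev <- car::leveneTest(y, g, center = if (center == "mean") mean else
    median)
  lev_p <- lev[["Pr(>F)"]][1L]
  structure(list(shapiro_p = c(a = sh_a, b = sh_b), levene_p = lev_p,
                 normality_ok = sh_a > alpha && sh_b > alpha,
                 equal_variance_ok = lev_p >= alpha, alpha = alpha,
                 center = center),
            class = "assumption_checks")
}

#' @export
print.assumption_checks <- function(x, ...) {
  cat(sprintf(
    "<assumption_checks> Shapiro-Wilk p: %.3g / %.3g (normality %s); ",
    x$shapiro_p[1L], x$shapiro_p[2L],
    if (x$normality_ok) "ok" else "violated"))
  cat(sprintf("Levene (%s-centred) p: %.3g (variances %s) at alpha %g\n",
              x$center, x$levene_p,
              if (x$equal_variance_ok) "equal" else "unequal", x$alpha))
  invisible(x)
}

#' Choose the between-group test from assumption checks
#'
#' Welch's t-test if and only if the variance-equality check failed;
#' Student's t-test otherwise.
#'
#' @param checks An [assumption_checks()] result.
#' @return `"welch_t"` or `"student_t"`.
#' @export
select_between_test <- function(checks) {
  stopifnot(inherits(checks, "assumption_checks"))
  if (checks$equal_variance_ok) "student_t" else "welch_t"
}

# variance-equality gate available on the summary path: two-sided F ratio
# test on sd_change^2 (Levene itself needs raw data)
variance_ratio_test <- function(a, b) {
  f <- a$sd_change^2 / b$sd_change^2
  p <- 2 * min(pf(f, a$n - 1, b$n - 1),
               pf(f, a$n - 1, b$n - 1, lower.tail = FALSE))
  list(statistic = f, p_value = min(p, 1))
}

#' Non-parametric sensitivity checks on raw change scores
#'
#' Wilcoxon signed-rank tests within each group and a Mann-Whitney U test
#' between groups, all two-sided. Exact distributions are used where the
#' sample sizes permit (n of at most `exact_max` and no ties); otherwise
#' the normal approximation with tie correction is applied and the result
#' is marked non-exact.
#'
#' @inheritParams assumption_checks
#' @param exact_max Largest sample size for which exact p-values are
#'   attempted (default 25).
#' @return List of `test_result`s: `wilcoxon_a`, `wilcoxon_b` (within each
#'   group) and `mann_whitney` (between groups, statistic = U).
#' @export
nonparametric_checks <- function(changes_a, changes_b, exact_max = 25L) {
  signed_rank <- function(z) {
    if (all(z == 0))
      stop("degenerate input: all change scores are zero", call. = FALSE)
    exact <- length(z) <= exact_max && !anyDuplicated(abs(z[z != 0]))
    w <- suppressWarnings(wilcox.test(z, exact = exact, correct = TRUE))
    test_result(unname(w$statistic), NA_real_, w$p.value, NA_real_,
                "wilcoxon", n = length(z), exact = exact)
  }
  exact_mw <- length(changes_a) <= exact_max &&
    length(changes_b) <= exact_max &&
    !anyDuplicated(c(changes_a, changes_b))
  mw <- suppressWarnings(wilcox.test(changes_a, changes_b,
                                     exact = exact_mw, correct = TRUE))
  list(wilcoxon_a = signed_rank(changes_a),
       wilcoxon_b = signed_rank(changes_b),
       mann_whitney = test_result(unname(mw$statistic),
                                  NA_real_, mw$p.value, NA_real_,
                                  "mann_whitney",
                                  n = length(changes_a) + length(changes_b),
                                  exact = exact_mw))
}

.mcid_table <- data.frame(
  scale = c("FMA-UE", "FIM", "MORE"),
  threshold_mcid = c(9.0, 22, NA),    # FMA-UE: lower bound of ~9-10 points
  threshold_mdc = c(5.2, NA, NA),
  stringsAsFactors = FALSE)

#' Annotate a mean change with MCID / MDC thresholds
#'
#' Compares the magnitude of a mean change score with published minimal
#' clinically important difference (MCID) and minimal detectable change
#' (MDC) thresholds: FMA-UE MCID 9 points (lower bound of the commonly
#' cited ~9-10 range for subacute stroke) and MDC 5.2 points (chronic
#' stroke); FIM total MCID 22 points (the motor subscore threshold,
#' ~17 points, applies to the subscore, not the total stored here); the
#' MORE scale has no published MCID, so its thresholds are reported as
#' unknown (`NA`).
#'
#' @param scale One of `"FMA-UE"`, `"FIM"`, `"MORE"`.
#' @param mean_change Mean change in scale points.
#' @return An object of class `mcid_annotation` with fields `scale`,
#'   `threshold_mcid`, `threshold_mdc`, `meets_mcid`, `exceeds_mdc`
#'   (booleans, `NA` where no threshold is published).
#' @export
#' @examples
#' annotate_mcid("FMA-UE", 9.38)
annotate_mcid <- function(scale, mean_change) {
  row <- .mcid_table[.mcid_table$scale == scale, ]
  if (nrow(row) == 0L)
    stop("unknown scale: ", scale, call. = FALSE)
  structure(list(
    scale = scale, mean_change = mean_change,
    threshold_mcid = row$threshold_mcid,
    threshold_mdc = row$threshold_mdc,
    meets_mcid = if (is.na(row$threshold_mcid)) NA else
      abs(mean_change) >= row$threshold_mcid,
    exceeds_mdc = if (is.na(row$threshold_mdc)) NA else
      abs(mean_change) > row$threshold_mdc),
    class = "mcid_annotation")
}

#' @export
print.mcid_annotation <- function(x, ...) {
  cat("<mcid_annotation> ", x$scale, ": change ",
      sprintf("%.2f", x$mean_change), " points; ", sep = "")
  if (is.na(x$threshold_mcid)) {
    cat("no published MCID (clinical significance not threshold-based)\n")
  } else {
    cat("MCID ", x$threshold_mcid, " (",
        if (isTRUE(x$meets_mcid)) "met" else "not met", ")", sep = "")
    if (!is.na(x$threshold_mdc))
      cat("; MDC ", x$threshold_mdc, " (",
          if (isTRUE(x$exceeds_mdc)) "exceeded" else "not exceeded", ")",
          sep = "")
    cat("\n")
  }
  invisible(x)
}
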