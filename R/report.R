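# Full trial analysis: assembles the within-group, assumption-check,
# between-group and MCID components into one report mirroring the layout of
# published feasibility-trial tables.

.is_summary_table <- function(x)
  is.data.frame(x) && all(c("scale", "group", "n", "mean_change",
                            "sd_change") %in% names(x))

.is_cohort_table <- function(x)
  is.data.frame(x) && all(c("scale", "group", "week1", "week3") %in%
                            names(x))

#' Run the complete feasibility-trial analysis
#'
#' For every clinical scale present: paired t-tests within each group,
#' a between-group comparison of change scores with the test selected by a
#' variance-equality check (Student's t when variances are compatible,
#' Welch's t otherwise), pooled-SD Cohen's d, and MCID/MDC annotation of
#' each group's mean change.
#'
#' Two input forms are accepted:
#' * a **summary table** (columns `scale`, `group`, `n`, `mean_change`,
#'   `sd_change`, e.g. [trial_summary()]): everything is computed from the
#'   summary triples; the variance gate is the two-sided F ratio test,
#'   since Levene's test needs raw scores;
#' * a **cohort table** (columns `patient_id`, `group`, `scale`, `week1`,
#'   `week3`, e.g. [simulate_cohort()]): change scores are computed per
#'   patient, Shapiro-Wilk and Levene assumption checks gate the
#'   between-group test, and Wilcoxon / Mann-Whitney sensitivity checks are
#'   added.
#'
#' @param x Summary or cohort data frame (see above).
#' @param alpha Significance level for assumption gating (default 0.05).
#' @param levene_center Centring for Levene's test on the raw path
#'   (`"mean"`, classic, or `"median"`).
#' @return An object of class `trial_analysis`: list with data frames
#'   `within` (one row per scale x group), `between` (one row per scale,
#'   both Student and Welch results plus the selected method), `mcid`, and
#'   -- on the raw path -- `assumptions` and `nonparametric`.
#' @export
#' @examples
#' run_full_analysis(trial_summary())
run_full_analysis <- function(x, alpha = 0.05,
                              levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  if (!is.data.frame(x) || nrow(x) == 0L)
    stop("input is empty or not a data frame", call. = FALSE)
  raw_path <- .is_cohort_table(x)
  if (!raw_path && !.is_summary_table(x))
    stop("input must be a summary table (scale, group, n, mean_change, ",
         "sd_change) or a cohort table (patient_id, group, scale, week1, ",
         "week3)", call. = FALSE)

  changes <- NULL
  if (raw_path) {
    changes <- x
    changes$change <- changes$week3 - changes$week1
    summaries <- summarize_cohort(x)
  } else summaries <- x
  summaries$group <- as.character(summaries$group)

  scales <- unique(summaries$scale)
  groups <- unique(summaries$group)
  if (length(groups) != 2L)
    stop("exactly two groups are required, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  for (sc in scales) for (g in groups)
    if (sum(summaries$scale == sc & summaries$group == g) != 1L)
      stop("missing or duplicated cell: scale ", sc, ", group ", g,
           call. = FALSE)

  cell <- function(sc, g) {
    r <- summaries[summaries$scale == sc & summaries$group == g, ]
    group_summary(sc, g, r$n, r$mean_change, r$sd_change)
  }

  within <- do.call(rbind, lapply(scales, function(sc)
    do.call(rbind, lapply(groups, function(g) {
      s <- cell(sc, g); r <- paired_t_from_summary(s)
      data.frame(scale = sc, group = g, n = s$n,
                 mean_change = s$mean_change, sd_change = s$sd_change,
                 t = r$statistic, df = r$df, p = r$p_value,
                 d = r$effect_size_d)
    }))))

  assumptions <- NULL; nonpar <- NULL
  between <- do.call(rbind, lapply(scales, function(sc) {
    a <- cell(sc, groups[1L]); b <- cell(sc, groups[2L])
    st <- student_t_between(a, b)
    we <- welch_t_between(a, b)
    if (raw_path) {
      ch_a <- changes$change[changes$scale == sc &
                               changes$group == groups[1L]]
      ch_b <- changes$change[changes$scale == sc &
                               changes$group == groups[2L]]
      ck <- assumption_checks(ch_a, ch_b, alpha = alpha,
                              center = levene_center)
      sel <- select_between_test(ck)
      assumptions <<- rbind(assumptions, data.frame(
        scale = sc, shapiro_p_a = ck$shapiro_p[["a"]],
        shapiro_p_b = ck$shapiro_p[["b"]], levene_p = ck$levene_p,
        normality_ok = ck$normality_ok,
        equal_variance_ok = ck$equal_variance_ok))
      np <- nonparametric_checks(ch_a, ch_b)
      nonpar <<- rbind(nonpar, data.frame(
        scale = sc, wilcoxon_p_a = np$wilcoxon_a$p_value,
        wilcoxon_p_b = np$wilcoxon_b$p_value,
        mann_whitney_U = np$mann_whitney$statistic,
        mann_whitney_p = np$mann_whitney$p_value))
    } else {
      vr <- variance_ratio_test(a, b)
      sel <- if (vr$p_value >= alpha) "student_t" else "welch_t"
    }
    picked <- if (sel == "welch_t") we else st
    data.frame(scale = sc, student_t = st$statistic, student_p = st$p_value,
               welch_t = we$statistic, welch_df = we$df,
               welch_p = we$p_value, selected = sel,
               t = picked$statistic, df = picked$df, p = picked$p_value,
               d = st$effect_size_d)
  }))

  known <- intersect(scales, .mcid_table$scale)
  mcid <- do.call(rbind, lapply(known, function(sc)
    do.call(rbind, lapply(groups, function(g) {
      ann <- annotate_mcid(sc, cell(sc, g)$mean_change)
      data.frame(scale = sc, group = g, mean_change = ann$mean_change,
                 threshold_mcid = ann$threshold_mcid,
                 threshold_mdc = ann$threshold_mdc,
                 meets_mcid = ann$meets_mcid, exceeds_mdc = ann$exceeds_mdc)
    }))))

  structure(list(within = within, between = between, mcid = mcid,
                 assumptions = assumptions, nonparametric = nonpar,
                 input = if (raw_path) "raw" else "summary", alpha = alpha),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, digits = 3, ...) {
  cat("Feasibility-trial analysis (", x$input, " path, alpha ", x$alpha,
      ")\n\n", sep = "")
  cat("Within-group paired t-tests:\n")
  w <- x$within
  w$t <- round(w$t, 2); w$d <- round(w$d, 2); w$p <- signif(w$p, 3)
  print(w[, c("scale", "group", "n", "mean_change", "sd_change", "t",
              "df", "p", "d")], row.names = FALSE)
  cat("\nBetween-group comparison of change scores:\n")
  b <- x$between
  b$t <- round(b$t, 2); b$df <- round(b$df, 2); b$p <- signif(b$p, 3)
  b$d <- round(b$d, 2)
  print(b[, c("scale", "selected", "t", "df", "p", "d")],
        row.names = FALSE)
  if (!is.null(x$assumptions)) {
    cat("\nAssumption checks:\n")
    a <- x$assumptions
    a[, 2:4] <- signif(a[, 2:4], 3)
    print(a, row.names = FALSE)
  }
  if (!is.null(x$nonparametric)) {
    cat("\nNon-parametric sensitivity checks:\n")
    np <- x$nonparametric
    np[, c(2, 3, 5)] <- signif(np[, c(2, 3, 5)], 3)
    print(np, row.names = FALSE)
  }
  cat("\nMCID / MDC annotation:\n")
  print(x$mcid, row.names = FALSE)
  invisible(x)
}

#' Write a trial analysis to CSV and JSON files
#'
#' Writes `within.csv`, `between.csv`, `mcid.csv` (plus `assumptions.csv`
#' and `nonparametric.csv` on the raw path) and a combined `analysis.json`
#' into `dir`.
#'
#' @param analysis A [run_full_analysis()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "trial_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- c("within", "between", "mcid", "assumptions", "nonparametric")
  paths <- character(0)
  for (p in parts) {
    if (is.null(analysis[[p]])) next
    f <- file.path(dir, paste0(p, ".csv"))
    write.csv(analysis[[p]], f, row.names = FALSE)
    paths <- c(paths, f)
  }
  jf <- file.path(dir, "analysis.json")
  jsonlite::write_json(analysis[!sapply(analysis, is.null)], jf,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(paths, jf))
}
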