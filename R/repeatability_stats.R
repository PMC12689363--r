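# Test-retest and longitudinal statistics: within-subject coefficient of
# variation, repeated-measures correlation, one-way repeated-measures ANOVA
# with Bonferroni-corrected post-hoc paired contrasts. Standard
# normality/rank tests are thin delegations to stats::.

#' Within-subject coefficient of variation (wCV)
#'
#' Test-retest repeatability of a biomarker: with `s_i` and `m_i` the
#' standard deviation and mean of subject `i`'s sessions,
#' `wCV = sqrt(mean_i (s_i / m_i)^2) * 100` (percent) — the root mean of
#' per-subject squared coefficients of variation. For two-session designs
#' this coincides with the paired-difference form
#' `sqrt(mean_i (d_i^2 / 2) / m_i^2) * 100` with `d_i` the within-subject
#' difference, available via `method = "difference"` as a cross-check.
#'
#' @param table A biomarker tibble ([read_biomarker_table()] contract).
#' @param biomarker Biomarker name to evaluate.
#' @param roi ROI name to evaluate.
#' @param method `"rms"` (default) or `"difference"` (2-session designs).
#' @return A `wcv_result`: `wcv` (percent), `n_subjects` used,
#'   `n_excluded` subjects dropped for having fewer than 2 sessions,
#'   `biomarker_name`, `roi_name`.
#' @export
wcv <- function(table, biomarker, roi, method = c("rms", "difference")) {
  method <- match.arg(method)
  tbl <- dplyr::filter(table, .data$biomarker_name == biomarker,
                       .data$roi_name == roi)
  if (nrow(tbl) == 0) stop("no records for this biomarker/ROI")
  if (any(tbl$value <= 0)) stop("wCV requires strictly positive values")
  per <- tbl |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$value),
                     s = stats::sd(.data$value),
                     d = diff(range(.data$value)),
                     .by = "subject_id")
  n_excluded <- sum(per$n < 2)
  per <- dplyr::filter(per, .data$n >= 2)
  if (nrow(per) < 2) stop("wCV needs at least 2 subjects with >= 2 sessions")
  wcv_val <- switch(method,
    rms = sqrt(mean((per$s / per$m)^2)) * 100,
    difference = {
      if (any(per$n != 2)) stop("difference method requires exactly 2 sessions")
      sqrt(mean(per$d^2 / (2 * per$m^2))) * 100
    })
  structure(list(wcv = wcv_val, n_subjects = nrow(per),
                 n_excluded = n_excluded, biomarker_name = biomarker,
                 roi_name = roi, method = method),
            class = "wcv_result")
}

#' @export
print.wcv_result <- function(x, ...) {
  cat(sprintf("wCV(%s, %s) = %.2f%% over %d subjects (%d excluded)\n",
              x$biomarker_name, x$roi_name, x$wcv, x$n_subjects,
              x$n_excluded))
  invisible(x)
}

#' @export
tidy.wcv_result <- function(x, ...) {
  tibble::tibble(biomarker_name = x$biomarker_name, roi_name = x$roi_name,
                 wcv_percent = x$wcv, n_subjects = x$n_subjects,
                 n_excluded = x$n_excluded, method = x$method)
}

#' Repeated-measures correlation
#'
#' The common within-subject association between two variables measured
#' repeatedly on the same subjects: each subject's means are subtracted
#' from `x` and `y`, the pooled residuals are Pearson-correlated, and the
#' test uses `t = r * sqrt(dof / (1 - r^2))` with
#' `dof = N - n_subjects - 1` (equivalent to ANCOVA with subject
#' indicators). Removing subject means strips the between-subject
#' component, so `r` reflects how the variables co-vary within subjects.
#'
#' @param data Data frame of repeated observations.
#' @param subject,x,y Column names (strings) of the subject identifier and
#'   the two variables.
#' @return An `rmcorr_result`: `r`, `dof`, `p` (two-sided), `n_obs`,
#'   `n_subjects`, and `valid` (`FALSE`, with `r = NA`, when either
#'   variable has zero within-subject variance).
#' @export
rm_correlation <- function(data, subject = "subject_id", x = "x", y = "y") {
  stopifnot(all(c(subject, x, y) %in% names(data)))
  df <- data.frame(s = as.character(data[[subject]]),
                   x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  df <- df[stats::complete.cases(df), ]
  k <- length(unique(df$s))
  n <- nrow(df)
  dof <- n - k - 1
  if (dof < 1) stop("not enough observations: dof = N - n_subjects - 1 < 1")
  rx <- df$x - stats::ave(df$x, df$s)
  ry <- df$y - stats::ave(df$y, df$s)
  if (sum(rx^2) == 0 || sum(ry^2) == 0) {
    return(structure(list(valid = FALSE, r = NA_real_, dof = dof,
                          p = NA_real_, n_obs = n, n_subjects = k),
                     class = "rmcorr_result"))
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(dof / (1 - r^2))
    2 * stats::pt(-abs(tval), dof)
  }
  structure(list(valid = TRUE, r = r, dof = dof, p = p, n_obs = n,
                 n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  if (!x$valid) cat("rm-correlation undefined (zero within-subject variance)\n")
  else cat(sprintf("rm-correlation r = %.3f (dof = %d, p = %.4g)\n",
                   x$r, x$dof, x$p))
  invisible(x)
}

#' @export
tidy.rmcorr_result <- function(x, ...) {
  tibble::tibble(r = x$r, dof = x$dof, p.value = x$p, n_obs = x$n_obs,
                 n_subjects = x$n_subjects, valid = x$valid)
}

#' @export
glance.rmcorr_result <- function(x, ...) tidy.rmcorr_result(x, ...)

#' One-way repeated-measures ANOVA with Bonferroni post-hoc contrasts
#'
#' Classical within-subject decomposition on complete cases:
#' `SS_total = SS_subject + SS_time + SS_error`, `F = MS_time / MS_error`
#' with `df_time = t - 1` and `df_error = (t - 1)(n - 1)`. Subjects missing
#' any timepoint are dropped (and counted). Each requested contrast is a
#' paired t-test; Bonferroni correction multiplies its p-value by the
#' number of contrasts, capped at 1.
#'
#' @param data Data frame with one value per subject and timepoint.
#' @param subject,timepoint,value Column names (strings).
#' @param contrasts List of length-2 character vectors of timepoint labels
#'   to test post hoc, e.g. `list(c("baseline", "week3"))`. `NULL` skips
#'   post-hoc testing.
#' @return An `rmanova_result`: `F`, `df_time`, `df_error`, `p`, the
#'   sums of squares, `n_subjects`, `n_dropped`, and a `posthoc` tibble
#'   (contrast, t, df, p_uncorrected, p_bonferroni).
#' @export
rm_anova <- function(data, subject = "subject_id", timepoint = "session",
                     value = "value", contrasts = NULL) {
  stopifnot(all(c(subject, timepoint, value) %in% names(data)))
  df <- data.frame(s = as.character(data[[subject]]),
                   t = as.character(data[[timepoint]]),
                   v = as.numeric(data[[value]]))
  if (anyDuplicated(paste(df$s, df$t, sep = "\r"))) {
    stop("one value per subject and timepoint is required")
  }
  tps <- sort(unique(df$t))
  if (length(tps) < 2) stop("at least 2 timepoints are required")
  wide <- tidyr::pivot_wider(tibble::as_tibble(df), names_from = "t",
                             values_from = "v")
  complete <- stats::complete.cases(wide[tps])
  n_dropped <- sum(!complete)
  wide <- wide[complete, ]
  n <- nrow(wide)
  if (n < 2) stop("fewer than 2 complete subjects")
  m <- as.matrix(wide[tps])
  grand <- mean(m)
  ss_subject <- length(tps) * sum((rowMeans(m) - grand)^2)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_subject - ss_time
  df_time <- length(tps) - 1L
  df_error <- df_time * (n - 1L)
  ms_time <- ss_time / df_time
  ms_error <- ss_error / df_error
  F_stat <- if (ms_error > 0) ms_time / ms_error else
    ifelse(ms_time > 0, Inf, 0)
  p <- stats::pf(F_stat, df_time, df_error, lower.tail = FALSE)
  posthoc <- NULL
  if (!is.null(contrasts)) {
    m_con <- length(contrasts)
    posthoc <- dplyr::bind_rows(lapply(contrasts, function(ct) {
      stopifnot(length(ct) == 2, all(ct %in% tps))
      tt <- stats::t.test(m[, ct[1]], m[, ct[2]], paired = TRUE)
      tibble::tibble(contrast = paste(ct, collapse = " vs "),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_uncorrected = tt$p.value,
                     p_bonferroni = bonferroni_correct(tt$p.value, m_con))
    }))
  }
  structure(list(F = F_stat, df_time = df_time, df_error = df_error, p = p,
                 ss_subject = ss_subject, ss_time = ss_time,
                 ss_error = ss_error, n_subjects = n, n_dropped = n_dropped,
                 timepoints = tps, posthoc = posthoc),
            class = "rmanova_result")
}

#' Bonferroni correction by multiplication
#'
#' `p_corrected = min(1, m * p)` for `m` comparisons.
#'
#' @param p Uncorrected p-value(s).
#' @param m Number of comparisons.
#' @return Corrected p-value(s).
#' @export
bonferroni_correct <- function(p, m) pmin(1, m * p)

#' @export
print.rmanova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g (%d subjects, %d dropped)\n",
              x$df_time, x$df_error, x$F, x$p, x$n_subjects, x$n_dropped))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' @export
tidy.rmanova_result <- function(x, ...) {
  main <- tibble::tibble(term = "time", statistic = x$F, df = x$df_time,
                         df_error = x$df_error, p.value = x$p,
                         p.bonferroni = NA_real_)
  if (is.null(x$posthoc)) return(main)
  dplyr::bind_rows(main, tibble::tibble(
    term = x$posthoc$contrast, statistic = x$posthoc$t, df = x$posthoc$df,
    df_error = NA_real_, p.value = x$posthoc$p_uncorrected,
    p.bonferroni = x$posthoc$p_bonferroni))
}

#' @export
glance.rmanova_result <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_time = x$df_time,
                 df_error = x$df_error, p.value = x$p,
                 n_subjects = x$n_subjects, n_dropped = x$n_dropped)
}

#' Delegated standard hypothesis tests
#'
#' Thin pass-throughs to the standard routines in `stats::` for the tests
#' surrounding the bespoke statistics (normality screening and group
#' comparisons); nothing is re-implemented. Results are returned as a tidy
#' one-row tibble for the provenance report.
#'
#' @param x Numeric vector (first sample).
#' @param y Optional second sample (paired or unpaired tests).
#' @param test One of `"shapiro"`, `"t_paired"`, `"t_unpaired"`,
#'   `"wilcoxon_signed_rank"`.
#' @param ... Passed on to the underlying routine.
#' @return Tibble with `test`, `statistic`, `p.value`.
#' @export
delegated_test <- function(x, y = NULL,
                           test = c("shapiro", "t_paired", "t_unpaired",
                                    "wilcoxon_signed_rank"), ...) {
  test <- match.arg(test)
  res <- switch(test,
    shapiro = stats::shapiro.test(x),
    t_paired = stats::t.test(x, y, paired = TRUE, ...),
    t_unpaired = stats::t.test(x, y, paired = FALSE, ...),
    wilcoxon_signed_rank = stats::wilcox.test(x, y, paired = TRUE, ...))
  tibble::tibble(test = test, statistic = unname(res$statistic),
                 p.value = res$p.value)
}
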