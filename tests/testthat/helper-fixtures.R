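# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written from the definitions, independent of the package's
# production code paths.

scheme10 <- function() default_scheme()

noiseless_ivim <- function(f, D, Dstar, S0 = 1, scheme = scheme10()) {
  S0 * (f * exp(-scheme$bvalues * Dstar * 1e-3) +
          (1 - f) * exp(-scheme$bvalues * D * 1e-3))
}

# Independent AICc evaluation straight from the formula.
oracle_aicc <- function(ssr, n, k) n * log(ssr / n) + 2 * k +
  2 * k * (k + 1) / (n - k - 1)

# Brute-force mono-exponential least squares on a (S0, ADC) grid, refined by
# two rounds of grid shrinking; independent of the profiled production fit.
oracle_adc_grid <- function(b, s, adc_range = c(0, 5), s0_range = NULL) {
  if (is.null(s0_range)) s0_range <- c(0.2, 3) * max(s)
  best <- c(NA, NA, Inf)
  for (round in 1:4) {
    adcs <- seq(adc_range[1], adc_range[2], length.out = 61)
    s0s <- seq(s0_range[1], s0_range[2], length.out = 61)
    for (a in adcs) for (s0 in s0s) {
      r <- s - s0 * exp(-b * a * 1e-3)
      ssr <- sum(r * r)
      if (ssr < best[3]) best <- c(a, s0, ssr)
    }
    da <- diff(adc_range) / 20; ds <- diff(s0_range) / 20
    adc_range <- c(max(0, best[1] - da), best[1] + da)
    s0_range <- c(max(1e-9, best[2] - ds), best[2] + ds)
  }
  list(ADC = best[1], S0 = best[2], ssr = best[3])
}

# Full simultaneous 4-parameter IVIM NLS oracle (Levenberg-Marquardt).
oracle_ivim_nls <- function(b, s, start = c(S0 = 1, f = 0.1, D = 1, Ds = 20)) {
  res_fun <- function(p) {
    s - p[1] * (p[2] * exp(-b * p[4] * 1e-3) + (1 - p[2]) * exp(-b * p[3] * 1e-3))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = res_fun,
                            lower = c(1e-6, 0, 1e-6, 3),
                            upper = c(10, 0.999, 4, 100),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::setNames(fit$par, c("S0", "f", "D", "Dstar")))
}

# ANCOVA oracle for the repeated-measures correlation: regression of y on x
# plus subject indicators; r is the sign-carrying square root of the partial
# correlation of the x term.
oracle_rmcorr <- function(subject, x, y) {
  subject <- factor(subject)
  fit <- stats::lm(y ~ x + subject)
  fit0 <- stats::lm(y ~ subject)
  ss_full <- sum(stats::residuals(fit)^2)
  ss_red <- sum(stats::residuals(fit0)^2)
  r2 <- (ss_red - ss_full) / ss_red
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(r2)
  dof <- stats::df.residual(fit)
  tval <- r * sqrt(dof / (1 - r^2))
  list(r = r, dof = dof, p = 2 * stats::pt(-abs(tval), dof))
}

# From-scratch sums-of-squares enumeration for the one-way RM ANOVA.
oracle_rm_anova <- function(m) {  # m: subjects x timepoints matrix
  n <- nrow(m); t <- ncol(m); grand <- mean(m)
  ss_sub <- t * sum((rowMeans(m) - grand)^2)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_sub - ss_time
  df_time <- t - 1; df_err <- (t - 1) * (n - 1)
  F <- (ss_time / df_time) / (ss_err / df_err)
  list(F = F, df_time = df_time, df_error = df_err,
       p = stats::pf(F, df_time, df_err, lower.tail = FALSE),
       ss_time = ss_time, ss_error = ss_err)
}

# Small deterministic biomarker table.
toy_biomarker_table <- function(n_subjects = 6, sessions = c("s1", "s2"),
                                rois = "cervix",
                                biomarkers = c("D", "f", "p_IVIM"),
                                value_fun = function(i, s, r, b) 1 + 0.1 * i) {
  grid <- expand.grid(subject_id = sprintf("sub%02d", seq_len(n_subjects)),
                      session = sessions, roi_name = rois,
                      biomarker_name = biomarkers,
                      stringsAsFactors = FALSE)
  grid$group <- "healthy"
  grid$value <- mapply(value_fun, match(grid$subject_id, unique(grid$subject_id)),
                       grid$session, grid$roi_name, grid$biomarker_name)
  tibble::as_tibble(grid[c("subject_id", "group", "session", "roi_name",
                           "biomarker_name", "value")])
}
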