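# Per-voxel estimation: mono-exponential fits on configurable b-value
# subsets (ADC_b0, ADC_b150) and the segmented bi-exponential IVIM fit with
# a b-value cut-off sweep selected by minimum sum of squared residuals.

#' Fitting configuration
#'
#' Collects the knobs of the voxel-wise fits.
#'
#' @param cutoff_candidates b-value cut-offs (s/mm^2) swept by the segmented
#'   IVIM fit; the fit with the lowest full-decay sum of squared residuals
#'   wins, ties going to the lower cut-off. Default `c(100, 150, 300)`.
#' @param dstar_bounds Bounds on the pseudo-diffusion coefficient D*,
#'   um^2/ms. Default `c(3, 100)`: D* must exceed tissue D and cover
#'   capillary pseudo-diffusion.
#' @param d_bounds Bounds on the tissue diffusion coefficient D, um^2/ms.
#'   The upper default of 4 is just above free water at body temperature.
#' @param adc150_threshold Smallest b-value (s/mm^2) entering the
#'   perfusion-suppressed ADC fit (ADC_b150). Default 150.
#' @param ssr_floor_rel Relative noise floor epsilon; sums of squared
#'   residuals are floored at `(ssr_floor_rel)^2 * n * S(0)^2` before the
#'   AICc logarithm so that noiseless data cannot produce `log(0)`.
#' @param adc_bounds Search bounds for the ADC estimate, um^2/ms.
#' @return A `fit_config` object (a named list).
#' @export
fit_config <- function(cutoff_candidates = c(100, 150, 300),
                       dstar_bounds = c(3, 100),
                       d_bounds = c(1e-4, 4),
                       adc150_threshold = 150,
                       ssr_floor_rel = 1e-6,
                       adc_bounds = c(0, 10)) {
  stopifnot(length(dstar_bounds) == 2, all(dstar_bounds > 0),
            dstar_bounds[1] < dstar_bounds[2],
            length(d_bounds) == 2, all(d_bounds > 0),
            d_bounds[1] < d_bounds[2],
            length(adc_bounds) == 2, adc_bounds[1] >= 0,
            adc_bounds[1] < adc_bounds[2],
            is.numeric(cutoff_candidates), length(cutoff_candidates) >= 1,
            ssr_floor_rel >= 0)
  structure(list(cutoff_candidates = sort(cutoff_candidates),
                 dstar_bounds = dstar_bounds, d_bounds = d_bounds,
                 adc150_threshold = adc150_threshold,
                 ssr_floor_rel = ssr_floor_rel,
                 adc_bounds = adc_bounds),
            class = "fit_config")
}

invalid_adc_fit <- function(b_min, reason) {
  structure(list(valid = FALSE, reason = reason, params = NULL, ssr = NA_real_,
                 n_points = 0L, n_params = 2L, b_min = b_min),
            class = "adc_fit")
}

# Profiled least squares for the mono-exponential: for a trial ADC the
# optimal S0 has the closed form sum(S e) / sum(e^2) with e = exp(-b ADC
# 1e-3), so the 2-parameter NLS reduces to a 1-D minimisation over ADC.
adc_profile_ssr <- function(adc, b, s) {
  e <- exp(-b * adc * 1e-3)
  s0 <- sum(s * e) / sum(e * e)
  r <- s - s0 * e
  sum(r * r)
}

#' Fit the mono-exponential ADC model to one voxel decay
#'
#' Nonlinear least squares of `S0 * exp(-b * ADC * 1e-3)` on the linear
#' signal scale, restricted to b-values at or above `b_min`. The closed-form
#' log-linear solution seeds the search; S0 is profiled out in closed form
#' and ADC minimised by coarse-grid bracketing plus golden-section
#' refinement, so the optimum of the full 2-parameter problem is returned.
#'
#' With `b_min = 0` this is the perfusion-sensitive ADC_b0; with
#' `b_min = 150` the perfusion-suppressed ADC_b150.
#'
#' @param decay Signal vector, one value per scheme b-value.
#' @param scheme An [acquisition_scheme()].
#' @param b_min Smallest b-value (s/mm^2) included in the fit.
#' @param config A [fit_config()].
#' @return An `adc_fit`: `params` ([adc_params()]), `ssr` over the fitted
#'   subset, `n_points`, `n_params = 2`, `b_min`, and `valid`. Voxels with
#'   fewer than 3 usable points or non-positive signal in the subset are
#'   returned invalid (flagged, not an error).
#' @export
fit_adc <- function(decay, scheme, b_min = 0, config = fit_config()) {
  b_all <- scheme$bvalues
  stopifnot(length(decay) == length(b_all))
  sel <- which(b_all >= b_min)
  if (length(sel) < 3) return(invalid_adc_fit(b_min, "fewer than 3 points"))
  b <- b_all[sel]; s <- decay[sel]
  if (any(!is.finite(s)) || any(s <= 0)) {
    return(invalid_adc_fit(b_min, "non-positive signal"))
  }
  # log-linear seed (exact for noiseless data)
  co <- stats::lm.fit(cbind(1, b), log(s))$coefficients
  adc0 <- min(max(-co[2] * 1e3, config$adc_bounds[1]), config$adc_bounds[2])
  # coarse grid guards against local minima in the profiled objective
  grid <- sort(unique(c(seq(config$adc_bounds[1], config$adc_bounds[2],
                            length.out = 41), adc0)))
  ssr_grid <- vapply(grid, adc_profile_ssr, numeric(1), b = b, s = s)
  i <- which.min(ssr_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  adc_hat <- if (hi > lo) {
    stats::optimize(adc_profile_ssr, c(lo, hi), b = b, s = s,
                    tol = 1e-10)$minimum
  } else grid[i]
  if (adc_profile_ssr(grid[i], b, s) < adc_profile_ssr(adc_hat, b, s)) {
    adc_hat <- grid[i]
  }
  adc_hat <- max(adc_hat, 0)
  e <- exp(-b * adc_hat * 1e-3)
  s0_hat <- sum(s * e) / sum(e * e)
  ssr <- sum((s - s0_hat * e)^2)
  structure(list(valid = TRUE, reason = NULL,
                 params = adc_params(s0_hat, adc_hat), ssr = ssr,
                 n_points = length(sel), n_params = 2L, b_min = b_min),
            class = "adc_fit")
}

invalid_ivim_fit <- function(reason) {
  structure(list(valid = FALSE, reason = reason, params = NULL,
                 ssr = NA_real_, n_params = 4L, cutoff = NA_real_,
                 per_cutoff_ssr = NULL, f_clamped = FALSE),
            class = "ivim_fit")
}

#' Fit the IVIM model to one voxel decay by the segmented approach
#'
#' For each candidate cut-off b*: (i) an unweighted log-linear fit on
#' b >= b* yields the tissue diffusion coefficient D and intercept A;
#' (ii) the perfusion fraction is `f = 1 - A / S(0)`, clamped to
#' `[0, 0.999]` (negative values to 0); (iii) with S0 pinned to the
#' measured b = 0 signal and (f, D) fixed, the pseudo-diffusion
#' coefficient D* is estimated by one-dimensional bounded least squares
#' over all b-values; (iv) the sum of squared residuals of the full
#' bi-exponential over all b-values scores the cut-off. The cut-off with
#' minimal SSR wins, ties broken toward the lower cut-off.
#'
#' @param decay Signal vector, one value per scheme b-value.
#' @param scheme An [acquisition_scheme()].
#' @param config A [fit_config()].
#' @return An `ivim_fit`: `params` (list with S0, f, D, Dstar), `ssr` over
#'   all b-values, `n_params = 4`, the selected `cutoff`, the named
#'   `per_cutoff_ssr` vector, and `f_clamped` recording whether the clamp
#'   engaged. Voxels with any non-positive signal are returned invalid.
#' @export
fit_ivim_segmented <- function(decay, scheme, config = fit_config()) {
  b <- scheme$bvalues
  stopifnot(length(decay) == length(b))
  if (any(!is.finite(decay)) || any(decay <= 0)) {
    return(invalid_ivim_fit("non-positive signal"))
  }
  s0_meas <- decay[which.min(b)]
  cands <- config$cutoff_candidates
  per <- stats::setNames(rep(NA_real_, length(cands)), as.character(cands))
  fits <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    hi <- which(b >= cands[i])
    if (length(hi) < 3) next
    co <- stats::lm.fit(cbind(1, b[hi]), log(decay[hi]))$coefficients
    D <- min(max(-co[2] * 1e3, config$d_bounds[1]), config$d_bounds[2])
    A <- exp(co[1])
    f_raw <- 1 - A / s0_meas
    f <- min(max(f_raw, 0), 0.999)
    lo_b <- max(config$dstar_bounds[1], D + 1e-6)
    obj <- function(ds) {
      r <- decay - ivim_signal_raw(s0_meas, f, D, ds, b)
      sum(r * r)
    }
    dstar <- if (f > 0 && lo_b < config$dstar_bounds[2]) {
      # coarse grid guards against multimodality before golden-section refine
      grid <- seq(lo_b, config$dstar_bounds[2], length.out = 50)
      vals <- vapply(grid, obj, numeric(1))
      gi <- which.min(vals)
      lo_g <- grid[max(1, gi - 1)]; hi_g <- grid[min(50, gi + 1)]
      cand <- stats::optimize(obj, c(lo_g, hi_g), tol = 1e-8)$minimum
      if (obj(cand) <= vals[gi]) cand else grid[gi]
    } else {
      lo_b
    }
    ssr <- obj(dstar)
    per[i] <- ssr
    fits[[i]] <- list(S0 = s0_meas, f = f, D = D, Dstar = dstar,
                      ssr = ssr, f_clamped = (f_raw < 0 || f_raw > 0.999))
  }
  if (all(is.na(per))) return(invalid_ivim_fit("no usable cutoff"))
  best <- which(per == min(per, na.rm = TRUE))[1]  # tie -> lower cutoff
  ft <- fits[[best]]
  structure(list(valid = TRUE, reason = NULL,
                 params = list(S0 = ft$S0, f = ft$f, D = ft$D,
                               Dstar = ft$Dstar),
                 ssr = ft$ssr, n_params = 4L, cutoff = cands[best],
                 per_cutoff_ssr = per, f_clamped = ft$f_clamped),
            class = "ivim_fit")
}

#' Fit ADC and IVIM models to every voxel of a volume
#'
#' Runs [fit_adc()] at `b_min = 0` and at the perfusion-suppression
#' threshold, [fit_ivim_segmented()], and the AICc comparison at each voxel
#' (optionally restricted to a mask), assembling parameter maps.
#'
#' @param dwi A `dwi_volume`.
#' @param mask Optional `roi_mask`; voxels with label 0 are skipped.
#' @param config A [fit_config()].
#' @param k_includes_sigma If `TRUE`, count the noise variance as an
#'   estimated parameter in both models (k = 3 vs 5); the default counts
#'   only the mean-model parameters (k = 2 for ADC, 4 for IVIM).
#' @return A `map_set`: named list of 3D arrays `D`, `f`, `Dstar`, `ADC_b0`,
#'   `ADC_b150`, `ssr_adc`, `ssr_ivim`, `aicc_adc`, `aicc_ivim`, `valid`
#'   (logical), `preference` (0/1/2 codes), plus `voxel_size`, `n_b`, and
#'   counts of excluded and f-clamped voxels.
#' @export
fit_dwi_volume <- function(dwi, mask = NULL, config = fit_config(),
                           k_includes_sigma = FALSE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$signal)[1:3]
  n_b <- length(dwi$scheme$bvalues)
  in_mask <- if (is.null(mask)) array(TRUE, d) else mask$labels != 0
  nm <- c("D", "f", "Dstar", "ADC_b0", "ADC_b150", "ssr_adc", "ssr_ivim",
          "aicc_adc", "aicc_ivim")
  maps <- stats::setNames(lapply(nm, function(x) array(NA_real_, d)), nm)
  valid <- array(FALSE, d)
  pref <- array(0L, d)
  n_clamped <- 0L
  sig <- matrix(dwi$signal, prod(d), n_b)
  k_adc <- 2L + as.integer(k_includes_sigma)
  k_ivim <- 4L + as.integer(k_includes_sigma)
  for (v in which(in_mask)) {
    decay <- sig[v, ]
    a0 <- fit_adc(decay, dwi$scheme, b_min = 0, config = config)
    iv <- fit_ivim_segmented(decay, dwi$scheme, config = config)
    a150 <- fit_adc(decay, dwi$scheme, b_min = config$adc150_threshold,
                    config = config)
    if (!a0$valid || !iv$valid) next
    valid[v] <- TRUE
    maps$D[v] <- iv$params$D
    maps$f[v] <- iv$params$f
    maps$Dstar[v] <- iv$params$Dstar
    maps$ADC_b0[v] <- a0$params$ADC
    if (a150$valid) maps$ADC_b150[v] <- a150$params$ADC
    maps$ssr_adc[v] <- a0$ssr
    maps$ssr_ivim[v] <- iv$ssr
    if (iv$f_clamped) n_clamped <- n_clamped + 1L
    cmp <- compare_voxel(a0, iv, n = n_b, s0 = decay[1],
                         ssr_floor_rel = config$ssr_floor_rel,
                         k_adc = k_adc, k_ivim = k_ivim)
    maps$aicc_adc[v] <- cmp$aicc_adc
    maps$aicc_ivim[v] <- cmp$aicc_ivim
    pref[v] <- if (cmp$preferred == "IVIM") 2L else 1L
  }
  structure(c(maps, list(valid = valid, preference = pref,
                         voxel_size = dwi$voxel_size, n_b = n_b,
                         n_excluded = sum(in_mask) - sum(valid),
                         n_f_clamped = n_clamped)),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  d <- dim(x$valid)
  cat(sprintf(
    "IVIM/ADC map set %d x %d x %d: %d valid, %d excluded, %d f-clamped\n",
    d[1], d[2], d[3], sum(x$valid), x$n_excluded, x$n_f_clamped))
  cat(sprintf("IVIM preferred in %d voxels, ADC in %d\n",
              sum(x$preference == 2L), sum(x$preference == 1L)))
  invisible(x)
}

#' Tidy a map set into one row per voxel
#'
#' @param x A `map_set` from [fit_dwi_volume()].
#' @param ... Unused.
#' @return A tibble with voxel indices, parameter estimates, model SSRs,
#'   AICc values and the preference code, valid voxels only.
#' @export
tidy.map_set <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  v <- which(x$valid)
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    D = x$D[v], f = x$f[v], Dstar = x$Dstar[v],
    ADC_b0 = x$ADC_b0[v], ADC_b150 = x$ADC_b150[v],
    delta_ADC = x$ADC_b0[v] - x$ADC_b150[v],
    ssr_adc = x$ssr_adc[v], ssr_ivim = x$ssr_ivim[v],
    aicc_adc = x$aicc_adc[v], aicc_ivim = x$aicc_ivim[v],
    preferred = dplyr::if_else(x$preference[v] == 2L, "IVIM", "ADC"))
}
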