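# Corrected Akaike information criterion per voxel, model preference maps,
# and the p_IVIM biomarker.

#' Corrected Akaike information criterion from a least-squares fit
#'
#' `AICc = n * ln(ssr / n) + 2k + 2k(k + 1) / (n - k - 1)`, the small-sample
#' corrected criterion for a Gaussian least-squares fit with `k` estimated
#' mean-model parameters on `n` data points. A lower AICc indicates the
#' statistically better characterisation of the signal.
#'
#' @param ssr Sum of squared residuals (signal units squared).
#' @param n Number of data points; must exceed `k + 1` or the correction
#'   term is undefined.
#' @param k Number of estimated parameters.
#' @param ssr_floor Floor applied to `ssr` before the logarithm, so that a
#'   perfect (noiseless) fit yields a finite value rather than `log(0)`.
#' @return The AICc value (dimensionless).
#' @examples
#' aicc(0.01, 10, 2)   # 10*log(0.001) + 4 + 12/7
#' aicc(0.01, 10, 4)   # 10*log(0.001) + 8 + 8
#' @export
aicc <- function(ssr, n, k, ssr_floor = 0) {
  stopifnot(is.numeric(ssr), is.numeric(n), is.numeric(k), ssr >= 0,
            ssr_floor >= 0)
  if (n <= k + 1) {
    stop(sprintf("AICc undefined for n = %d, k = %d (need n > k + 1)", n, k))
  }
  ssr <- max(ssr, ssr_floor)
  if (ssr <= 0) stop("ssr is zero and no positive floor was supplied")
  n * log(ssr / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare the ADC and IVIM fits of one voxel by AICc
#'
#' Both SSRs must be computed over the same `n` b-values (the full decay).
#' Before the logarithm, each SSR is floored at
#' `(ssr_floor_rel)^2 * n * s0^2` — a per-point relative noise proxy — so
#' noiseless voxels, where both models fit exactly, floor to equal AICc
#' penalty-difference and the tie rule applies. Preference is by strict
#' inequality; an exact tie goes to the simpler ADC model (parsimony).
#'
#' @param adc_fit An `adc_fit` with `b_min = 0` (fitted over all b-values).
#' @param ivim_fit An `ivim_fit`.
#' @param n Number of b-values both SSRs were computed over.
#' @param s0 Measured b = 0 signal, used for the SSR floor.
#' @param ssr_floor_rel Relative floor epsilon (see [fit_config()]).
#' @param k_adc,k_ivim Parameter counts (defaults 2 and 4; the noise
#'   variance is not counted).
#' @return A `model_comparison`: `aicc_adc`, `aicc_ivim`,
#'   `preferred` ("ADC" or "IVIM"), `delta = aicc_adc - aicc_ivim`, and
#'   `valid`. If either fit is invalid the comparison is invalid.
#' @export
compare_voxel <- function(adc_fit, ivim_fit, n, s0 = NULL,
                          ssr_floor_rel = 1e-6, k_adc = 2L, k_ivim = 4L) {
  if (is.null(adc_fit) || is.null(ivim_fit) ||
      !isTRUE(adc_fit$valid) || !isTRUE(ivim_fit$valid)) {
    return(structure(list(valid = FALSE, aicc_adc = NA_real_,
                          aicc_ivim = NA_real_, preferred = NA_character_,
                          delta = NA_real_),
                     class = "model_comparison"))
  }
  if (is.null(s0)) s0 <- adc_fit$params$S0
  floor_val <- ssr_floor_rel^2 * n * s0^2
  a_adc <- aicc(adc_fit$ssr, n, k_adc, ssr_floor = floor_val)
  a_ivim <- aicc(ivim_fit$ssr, n, k_ivim, ssr_floor = floor_val)
  preferred <- if (a_ivim < a_adc) "IVIM" else "ADC"
  structure(list(valid = TRUE, aicc_adc = a_adc, aicc_ivim = a_ivim,
                 preferred = preferred, delta = a_adc - a_ivim),
            class = "model_comparison")
}

#' Model preference map from a fitted volume
#'
#' @param maps A `map_set` from [fit_dwi_volume()].
#' @param mask Optional `roi_mask`; voxels outside it are coded 0.
#' @return A `preference_map`: integer `codes` (0 = invalid, 1 = ADC
#'   preferred, 2 = IVIM preferred) and `n_valid`.
#' @export
build_preference_map <- function(maps, mask = NULL) {
  stopifnot(inherits(maps, "map_set"))
  codes <- maps$preference
  if (!is.null(mask)) {
    stopifnot(all(dim(mask$labels) == dim(codes)))
    codes[mask$labels == 0L] <- 0L
  }
  structure(list(codes = codes, n_valid = sum(codes != 0L)),
            class = "preference_map")
}

#' @export
print.preference_map <- function(x, ...) {
  cat(sprintf("Preference map: %d valid voxels (%d ADC, %d IVIM)\n",
              x$n_valid, sum(x$codes == 1L), sum(x$codes == 2L)))
  invisible(x)
}

#' p_IVIM: the fraction of ROI voxels better described by the IVIM model
#'
#' `p_IVIM = (# voxels with IVIM preferred) / (# valid voxels)` within the
#' ROI; invalid voxels are excluded from the denominator. With zero valid
#' voxels the biomarker is undefined and `NA` is returned (never 0).
#'
#' @param pref A `preference_map` (or a bare 0/1/2 code array).
#' @param roi An `roi_mask`.
#' @param label ROI label to evaluate.
#' @return A fraction in `[0, 1]`, or `NA_real_` if no voxel is valid.
#' @export
p_ivim <- function(pref, roi, label) {
  codes <- if (inherits(pref, "preference_map")) pref$codes else pref
  stopifnot(inherits(roi, "roi_mask"), all(dim(codes) == dim(roi$labels)))
  in_roi <- roi$labels == label
  n_valid <- sum(codes[in_roi] != 0L)
  if (n_valid == 0L) {
    warning(sprintf("p_IVIM undefined for label %d: no valid voxel", label))
    return(NA_real_)
  }
  sum(codes[in_roi] == 2L) / n_valid
}

#' Plot a slice of a model preference map
#'
#' @param object A `preference_map`.
#' @param slice Which axial (third-index) slice to draw.
#' @param ... Unused.
#' @return A ggplot raster: grey = invalid, blue = ADC preferred,
#'   red = IVIM preferred.
#' @export
autoplot.preference_map <- function(object, slice = 1, ...) {
  sl <- object$codes[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$code <- factor(sl[cbind(df$i, df$j)], levels = 0:2,
                    labels = c("invalid", "ADC", "IVIM"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(invalid = "grey85", ADC = "#3B6FB6", IVIM = "#C03A2B"),
      drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Model preference, slice %d", slice),
                  fill = "Preferred") +
    ggplot2::theme_minimal()
}
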