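# Closed-form forward models for the diffusion-weighted signal decay.
#
# Unit convention used throughout the package: diffusivities (D, D*, ADC) are
# stored and reported in um^2/ms, b-values in s/mm^2. The exponent of each
# decay is b[s/mm^2] * coef[um^2/ms] * 1e-3, since 1 um^2/ms = 1e-3 mm^2/s.

UM2MS_PER_SMM2 <- 1e-3

#' IVIM (bi-exponential) model parameters
#'
#' Container for the parameters of the intra-voxel incoherent motion model:
#' the signal with no diffusion weighting `S0`, the perfusion signal fraction
#' `f`, the tissue diffusion coefficient `D` and the pseudo-diffusion
#' coefficient `Dstar` of the fast (capillary) component.
#'
#' @param S0 Signal amplitude at b = 0, arbitrary units; must be positive.
#' @param f Perfusion signal fraction, dimensionless, in `[0, 1)`.
#' @param D Tissue diffusion coefficient, um^2/ms; `0 < D <= d_ceiling`.
#' @param Dstar Pseudo-diffusion coefficient, um^2/ms; must exceed `D`
#'   whenever `f > 0` (with `f = 0` the fast compartment carries no signal
#'   and the ordering constraint is not enforced).
#' @param d_ceiling Upper bound on `D`, um^2/ms. Defaults to 4, just above
#'   free water at body temperature.
#' @return An object of class `ivim_params`.
#' @seealso [ivim_signal()], [adc_params()]
#' @export
ivim_params <- function(S0, f, D, Dstar, d_ceiling = 4) {
  stopifnot(is.numeric(S0), is.numeric(f), is.numeric(D), is.numeric(Dstar))
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive and finite")
  if (!is.finite(f) || f < 0 || f >= 1) stop("f must lie in [0, 1)")
  if (!is.finite(D) || D <= 0 || D > d_ceiling) {
    stop(sprintf("D must lie in (0, %g] um^2/ms", d_ceiling))
  }
  if (f > 0 && (!is.finite(Dstar) || Dstar <= D)) {
    stop("Dstar must exceed D when f > 0")
  }
  structure(list(S0 = S0, f = f, D = D, Dstar = Dstar),
            class = "ivim_params")
}

#' ADC (mono-exponential) model parameters
#'
#' @param S0 Signal amplitude at b = 0, arbitrary units; must be positive.
#' @param ADC Apparent diffusion coefficient, um^2/ms; non-negative.
#' @return An object of class `adc_params`.
#' @seealso [adc_signal()], [ivim_params()]
#' @export
adc_params <- function(S0, ADC) {
  stopifnot(is.numeric(S0), is.numeric(ADC))
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be positive and finite")
  if (!is.finite(ADC) || ADC < 0) stop("ADC must be non-negative and finite")
  structure(list(S0 = S0, ADC = ADC), class = "adc_params")
}

#' Bi-exponential IVIM signal decay
#'
#' Evaluates `S(b) = S0 * (f * exp(-b * Dstar * 1e-3) +
#' (1 - f) * exp(-b * D * 1e-3))`, the intra-voxel incoherent motion model
#' in which a fraction `f` of the b = 0 signal decays with the fast
#' pseudo-diffusion coefficient `Dstar` and the remainder with the tissue
#' diffusion coefficient `D`.
#'
#' @param params An [ivim_params()] object.
#' @param b Numeric vector of b-values, s/mm^2, all non-negative.
#' @return Signal amplitudes, one per element of `b`.
#' @examples
#' p <- ivim_params(S0 = 1, f = 0.2, D = 1.0, Dstar = 30)
#' ivim_signal(p, c(0, 150, 800))
#' @export
ivim_signal <- function(params, b) {
  if (!inherits(params, "ivim_params")) {
    params <- do.call(ivim_params, unclass(params))
  }
  stopifnot(is.numeric(b))
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be finite and >= 0")
  params$S0 * (params$f * exp(-b * params$Dstar * UM2MS_PER_SMM2) +
                 (1 - params$f) * exp(-b * params$D * UM2MS_PER_SMM2))
}

#' Mono-exponential ADC signal decay
#'
#' Evaluates `S(b) = S0 * exp(-b * ADC * 1e-3)`.
#'
#' @param params An [adc_params()] object.
#' @param b Numeric vector of b-values, s/mm^2, all non-negative.
#' @return Signal amplitudes, one per element of `b`.
#' @export
adc_signal <- function(params, b) {
  if (!inherits(params, "adc_params")) {
    params <- do.call(adc_params, unclass(params))
  }
  stopifnot(is.numeric(b))
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be finite and >= 0")
  params$S0 * exp(-b * params$ADC * UM2MS_PER_SMM2)
}

# Raw bi-exponential evaluation without constructor validation; used in inner
# fitting loops where parameters are already known to be admissible.
ivim_signal_raw <- function(S0, f, D, Dstar, b) {
  S0 * (f * exp(-b * Dstar * UM2MS_PER_SMM2) +
          (1 - f) * exp(-b * D * UM2MS_PER_SMM2))
}

adc_signal_raw <- function(S0, ADC, b) {
  S0 * exp(-b * ADC * UM2MS_PER_SMM2)
}
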