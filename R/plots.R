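# Plotting helpers for fitted voxel decays and biomarker tables.

#' Plot a voxel decay with its ADC and IVIM fits
#'
#' @param decay Signal vector.
#' @param scheme An [acquisition_scheme()].
#' @param config A [fit_config()].
#' @return A ggplot of the measured points and both fitted curves on a log
#'   signal scale.
#' @export
plot_voxel_fit <- function(decay, scheme, config = fit_config()) {
  a0 <- fit_adc(decay, scheme, b_min = 0, config = config)
  iv <- fit_ivim_segmented(decay, scheme, config = config)
  b_grid <- seq(0, max(scheme$bvalues), length.out = 200)
  curves <- dplyr::bind_rows(
    if (a0$valid) tibble::tibble(
      b = b_grid, signal = adc_signal(a0$params, b_grid), model = "ADC"),
    if (iv$valid) tibble::tibble(
      b = b_grid,
      signal = ivim_signal_raw(iv$params$S0, iv$params$f, iv$params$D,
                               iv$params$Dstar, b_grid),
      model = "IVIM"))
  pts <- tibble::tibble(b = scheme$bvalues, signal = decay)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_point(data = pts, colour = "black") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b [s/mm^2]", y = "signal (log scale)",
                  colour = "Model") +
    ggplot2::theme_minimal()
}

#' Plot a biomarker over sessions or timepoints, one line per subject
#'
#' @param table A biomarker tibble.
#' @param biomarker Biomarker name.
#' @param roi ROI name.
#' @return A ggplot in the style of repeatability/longitudinal figures.
#' @export
plot_biomarker_sessions <- function(table, biomarker, roi) {
  df <- dplyr::filter(table, .data$biomarker_name == biomarker,
                      .data$roi_name == roi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$value,
                                   group = .data$subject_id,
                                   colour = .data$subject_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = biomarker, title = sprintf("%s in %s", biomarker, roi)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
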