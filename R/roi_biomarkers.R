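# ROI-level summary biomarkers: medians over whole ROIs and over
# model-preference-conditioned voxel subsets, deltaADC, ROI volume, and
# assembly into the long-format biomarker table.

median_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) NA_real_ else stats::median(x)
}

#' Summarise one ROI of a fitted map set
#'
#' Medians are taken over valid voxels only (even counts: mean of the two
#' central order statistics, the usual sample median). The perfusion-bias
#' statistic deltaADC is computed voxel-wise as `ADC_b0 - ADC_b150` and then
#' median-reduced — not as a difference of medians. Subset medians restrict
#' to IVIM-favoured voxels (code 2: D, f, D*) and, for the diffusivities, to
#' ADC-favoured voxels (code 1: ADC_b0, ADC_b150, D). ROI volume is
#' `n_voxels * voxel volume`, reported in cm^3.
#'
#' @param maps A `map_set` from [fit_dwi_volume()].
#' @param roi An `roi_mask` on the same grid.
#' @param label ROI label to summarise.
#' @param roi_name Name recorded in the summary; defaults to the mask's
#'   label-name map or the label number.
#' @return A one-row tibble (`roi_summary`): counts, whole-ROI medians,
#'   `p_ivim`, `median_delta_adc`, `volume_cm3`, the subset medians
#'   (`*_ivimfav`, `*_adcfav`), and a logical `flag_empty` set when the ROI
#'   contains no valid voxel (all medians `NA`; nothing is fabricated).
#' @export
summarize_roi <- function(maps, roi, label, roi_name = NULL) {
  stopifnot(inherits(maps, "map_set"), inherits(roi, "roi_mask"),
            all(dim(roi$labels) == dim(maps$valid)))
  if (is.null(roi_name)) {
    nm <- roi$label_names[[as.character(label)]]
    roi_name <- if (is.null(nm)) as.character(label) else nm
  }
  in_roi <- roi$labels == label
  n_voxels <- sum(in_roi)
  vsel <- in_roi & maps$valid
  n_valid <- sum(vsel)
  code <- maps$preference
  ivimfav <- vsel & code == 2L
  adcfav <- vsel & code == 1L
  delta <- maps$ADC_b0 - maps$ADC_b150
  vol_cm3 <- n_voxels * prod(maps$voxel_size) / 1e3
  tibble::tibble(
    roi_name = roi_name, label = as.integer(label),
    n_voxels = n_voxels, n_valid = n_valid,
    flag_empty = n_valid == 0L,
    median_D = median_or_na(maps$D[vsel]),
    median_f = median_or_na(maps$f[vsel]),
    median_Dstar = median_or_na(maps$Dstar[vsel]),
    median_ADC_b0 = median_or_na(maps$ADC_b0[vsel]),
    median_ADC_b150 = median_or_na(maps$ADC_b150[vsel]),
    median_delta_adc = median_or_na(delta[vsel]),
    p_ivim = if (n_valid == 0L) NA_real_ else sum(ivimfav) / n_valid,
    volume_cm3 = vol_cm3,
    n_ivimfav = sum(ivimfav),
    median_D_ivimfav = median_or_na(maps$D[ivimfav]),
    median_f_ivimfav = median_or_na(maps$f[ivimfav]),
    n_adcfav = sum(adcfav),
    median_D_adcfav = median_or_na(maps$D[adcfav]),
    median_ADC_b0_adcfav = median_or_na(maps$ADC_b0[adcfav]),
    median_ADC_b150_adcfav = median_or_na(maps$ADC_b150[adcfav]))
}

#' Preference-conditioned subset medians for one ROI
#'
#' Medians restricted to IVIM-favoured voxels (D, f) and ADC-favoured
#' voxels (ADC_b0, ADC_b150, D), as used to assess whether whole-ROI
#' summaries are biased by voxels the other model describes better.
#'
#' @param maps A `map_set`.
#' @param pref Optional `preference_map` overriding the codes carried by
#'   `maps` (e.g. after masking).
#' @param roi An `roi_mask`.
#' @param label ROI label.
#' @return A one-row tibble of subset counts and medians; empty subsets are
#'   `NA` with their count 0, for exclusion downstream.
#' @export
subset_summaries <- function(maps, pref = NULL, roi, label) {
  if (!is.null(pref)) {
    stopifnot(inherits(pref, "preference_map"))
    maps$preference <- pref$codes
  }
  summarize_roi(maps, roi, label) |>
    dplyr::select(dplyr::all_of(c(
      "roi_name", "label", "n_ivimfav", "median_D_ivimfav",
      "median_f_ivimfav", "n_adcfav", "median_D_adcfav",
      "median_ADC_b0_adcfav", "median_ADC_b150_adcfav")))
}

#' Summarise every labelled ROI of a mask
#'
#' @inheritParams summarize_roi
#' @return A tibble with one [summarize_roi()] row per non-zero label.
#' @export
summarize_all_rois <- function(maps, roi) {
  labs <- sort(setdiff(unique(as.vector(roi$labels)), 0L))
  dplyr::bind_rows(lapply(labs, function(l) summarize_roi(maps, roi, l)))
}

biomarker_names_std <- c("D", "f", "p_IVIM", "ADC_b0", "ADC_b150",
                         "delta_ADC", "volume")

#' Build a long-format biomarker table from ROI summaries
#'
#' Emits one record per (subject, session, roi, biomarker) for the standard
#' biomarker set `D, f, p_IVIM, ADC_b0, ADC_b150, delta_ADC, volume`,
#' taking whole-ROI medians. Flagged (empty-ROI) summaries contribute no
#' records. Key collisions are a hard error.
#'
#' @param summaries Tibble of [summarize_roi()] rows, with added identifier
#'   columns `subject_id`, `group` and `session`.
#' @return A biomarker tibble in the [read_biomarker_table()] contract.
#' @export
build_biomarker_table <- function(summaries) {
  need <- c("subject_id", "group", "session", "roi_name")
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop("summaries lack identifier columns: ", paste(missing, collapse = ", "))
  }
  src <- c(D = "median_D", f = "median_f", p_IVIM = "p_ivim",
           ADC_b0 = "median_ADC_b0", ADC_b150 = "median_ADC_b150",
           delta_ADC = "median_delta_adc", volume = "volume_cm3")
  long <- summaries |>
    dplyr::filter(!.data$flag_empty) |>
    dplyr::select(dplyr::all_of(c(need, unname(src)))) |>
    tidyr::pivot_longer(dplyr::all_of(unname(src)),
                        names_to = "biomarker_name", values_to = "value") |>
    dplyr::mutate(biomarker_name = names(src)[match(.data$biomarker_name, src)]) |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::select(dplyr::all_of(biomarker_cols))
  validate_biomarker_table(long)
}
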