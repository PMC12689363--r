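# Pipeline orchestration: simulate -> fit -> summarize -> stats, with a
# config object, structured logging and a provenance manifest per stage.
# The same functions back the thin command-line wrapper in inst/cli/.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every random stream derives from it.
#' @param fit A [fit_config()].
#' @param noise_model,snr_b0,geometry,dim Phantom options for the simulate
#'   stage (see [phantom_spec()]).
#' @param k_includes_sigma AICc parameter-counting convention, see
#'   [fit_dwi_volume()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, fit = fit_config(),
                       noise_model = "rician", snr_b0 = 50,
                       geometry = "pelvis_toy", dim = c(16, 16, 2),
                       k_includes_sigma = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), fit = fit,
                 noise_model = noise_model, snr_b0 = snr_b0,
                 geometry = geometry, dim = dim,
                 k_includes_sigma = k_includes_sigma),
            class = "run_config")
}

config_echo <- function(config) {
  list(out_dir = config$out_dir, seed = config$seed,
       noise_model = config$noise_model, snr_b0 = config$snr_b0,
       geometry = config$geometry, dim = config$dim,
       k_includes_sigma = config$k_includes_sigma,
       cutoff_candidates = config$fit$cutoff_candidates,
       dstar_bounds = config$fit$dstar_bounds,
       d_bounds = config$fit$d_bounds,
       adc150_threshold = config$fit$adc150_threshold,
       ssr_floor_rel = config$fit$ssr_floor_rel)
}

write_manifest <- function(config, stage, inputs = character(), extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(utils::packageVersion("ivimpref")),
                     config = config_echo(config),
                     input_md5 = as.list(tools::md5sum(inputs))),
                extra)
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_label_names <- function(out_dir) {
  path <- file.path(out_dir, "mask_labels.json")
  if (!file.exists(path)) return(NULL)
  jsonlite::read_json(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[ivimpref:%s] %s", stage, sprintf(...)))
}

#' Simulate stage: write a phantom file set
#'
#' Generates one phantom under the config's geometry/noise settings and
#' writes the DW volume, b-value file, class mask, ground-truth maps and a
#' manifest into `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  spec <- phantom_spec(geometry = config$geometry, dim = config$dim,
                       snr_b0 = config$snr_b0,
                       noise_model = config$noise_model, seed = config$seed)
  ph <- generate_phantom(spec)
  paths <- list(dwi = file.path(config$out_dir, "dwi.nii.gz"),
                bval = file.path(config$out_dir, "dwi.bval"),
                mask = file.path(config$out_dir, "mask.nii.gz"))
  write_dwi(ph$dwi, paths$dwi, paths$bval)
  write_mask(ph$mask, paths$mask, reference = ph$dwi)
  jsonlite::write_json(ph$mask$label_names,
                       file.path(config$out_dir, "mask_labels.json"),
                       auto_unbox = TRUE)
  truth_manifest <- write_maps(
    list(truth_S0 = ph$truth$S0, truth_f = ph$truth$f, truth_D = ph$truth$D,
         truth_Dstar = ph$truth$Dstar),
    ph$dwi, config$out_dir)
  log_stage("simulate", "wrote %d x %d x %d phantom, noise=%s snr=%g",
            dim(ph$mask$labels)[1], dim(ph$mask$labels)[2],
            dim(ph$mask$labels)[3], config$noise_model, config$snr_b0)
  write_manifest(config, "simulate",
                 inputs = unlist(paths),
                 extra = list(truth_files = truth_manifest$file))
  invisible(paths)
}

#' Fit stage: voxel-wise parameter and preference maps
#'
#' Reads the DW volume (and optional mask) from `out_dir`, fits both
#' models voxel-wise and writes D, f, D*, ADC_b0, ADC_b150, preference and
#' validity maps plus a manifest with exclusion counts.
#'
#' @param config A [run_config()].
#' @param dwi_path,bval_path,mask_path Input paths; default to the
#'   simulate-stage outputs in `out_dir`.
#' @return Invisibly, the `map_set`.
#' @export
run_fit <- function(config,
                    dwi_path = file.path(config$out_dir, "dwi.nii.gz"),
                    bval_path = file.path(config$out_dir, "dwi.bval"),
                    mask_path = file.path(config$out_dir, "mask.nii.gz")) {
  dwi <- read_dwi(dwi_path, bval_path)
  mask <- if (!is.null(mask_path) && file.exists(mask_path)) {
    read_mask(mask_path, dwi, label_names = read_label_names(config$out_dir))
  } else NULL
  maps <- fit_dwi_volume(dwi, mask = mask, config = config$fit,
                         k_includes_sigma = config$k_includes_sigma)
  pref <- build_preference_map(maps, mask)
  out <- write_maps(list(D = maps$D, f = maps$f, Dstar = maps$Dstar,
                         ADC_b0 = maps$ADC_b0, ADC_b150 = maps$ADC_b150,
                         valid = maps$valid * 1,
                         preference = pref$codes),
                    dwi, config$out_dir)
  log_stage("fit", "%d valid voxels, %d excluded, %d f-clamped",
            sum(maps$valid), maps$n_excluded, maps$n_f_clamped)
  write_manifest(config, "fit",
                 inputs = c(dwi_path, bval_path,
                            if (!is.null(mask)) mask_path),
                 extra = list(n_valid = sum(maps$valid),
                              n_excluded = maps$n_excluded,
                              n_f_clamped = maps$n_f_clamped,
                              map_files = out$file))
  invisible(maps)
}

#' Summarize stage: ROI biomarker table
#'
#' Summarises every labelled ROI of the mask over the fitted maps and
#' writes whole-ROI and subset summaries (one JSON per ROI) plus the
#' long-format biomarker CSV.
#'
#' @param config A [run_config()].
#' @param maps A `map_set` (from [run_fit()]); if `NULL` the maps are
#'   refitted from the files in `out_dir`.
#' @param subject_id,group,session Identifiers stamped on the records.
#' @return Invisibly, the biomarker tibble.
#' @export
run_summarize <- function(config, maps = NULL, subject_id = "sub01",
                          group = "healthy", session = "session1") {
  dwi <- read_dwi(file.path(config$out_dir, "dwi.nii.gz"),
                  file.path(config$out_dir, "dwi.bval"))
  mask <- read_mask(file.path(config$out_dir, "mask.nii.gz"), dwi,
                    label_names = read_label_names(config$out_dir))
  if (is.null(maps)) maps <- run_fit(config)
  summaries <- summarize_all_rois(maps, mask) |>
    dplyr::mutate(subject_id = subject_id, group = group, session = session)
  for (i in seq_len(nrow(summaries))) {
    row <- summaries[i, ]
    jsonlite::write_json(
      c(as.list(row), list(config = config_echo(config))),
      file.path(config$out_dir, sprintf("roi_%s.json", row$roi_name)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (row$flag_empty) {
      warning(sprintf("ROI '%s' has no valid voxel; flagged, no records",
                      row$roi_name))
    }
  }
  table <- build_biomarker_table(summaries)
  write_biomarker_table(table, file.path(config$out_dir, "biomarkers.csv"))
  log_stage("summarize", "%d ROI(s), %d biomarker records",
            nrow(summaries), nrow(table))
  write_manifest(config, "summarize",
                 inputs = file.path(config$out_dir, "biomarkers.csv"))
  invisible(table)
}

#' Stats stage: repeatability and longitudinal statistics
#'
#' Routes on the design found in the biomarker table: two sessions per
#' subject triggers the wCV (test-retest) block; three or more timepoints
#' trigger the repeated-measures ANOVA block with the default contrasts
#' first-vs-second and first-vs-third timepoint. The repeated-measures
#' correlation between `delta_ADC` and `f` (per-ROI medians) is computed
#' whenever subjects have multiple observations.
#'
#' @param config A [run_config()].
#' @param table A biomarker tibble; defaults to `biomarkers.csv` in
#'   `out_dir`.
#' @param rmcorr_pair Length-2 character vector naming the biomarkers to
#'   correlate within subjects (default `c("delta_ADC", "f")`).
#' @return A list with elements `wcv` (tibble or NULL), `anova` (list of
#'   `rmanova_result` or NULL), `rmcorr` (`rmcorr_result` or NULL); also
#'   written as `stats_report.json` and `stats_report.csv`.
#' @export
run_stats <- function(config,
                      table = read_biomarker_table(
                        file.path(config$out_dir, "biomarkers.csv")),
                      rmcorr_pair = c("delta_ADC", "f")) {
  sessions_per_subject <- table |>
    dplyr::distinct(.data$subject_id, .data$session) |>
    dplyr::count(.data$subject_id)
  n_sessions <- sort(unique(sessions_per_subject$n))
  all_sessions <- sort(unique(table$session))
  is_retest <- max(n_sessions) == 2
  is_longitudinal <- length(all_sessions) >= 3
  if (max(n_sessions) < 2) {
    stop("design detection failed: no subject has 2+ sessions/timepoints")
  }
  wcv_block <- NULL
  anova_block <- NULL
  rmcorr_block <- NULL
  if (is_retest) {
    combos <- table |> dplyr::distinct(.data$biomarker_name, .data$roi_name)
    wcv_block <- dplyr::bind_rows(purrr::pmap(combos, function(biomarker_name,
                                                               roi_name) {
      res <- tryCatch(wcv(table, biomarker_name, roi_name),
                      error = function(e) NULL)
      if (is.null(res)) NULL else tidy(res)
    }))
    log_stage("stats", "wCV block: %d biomarker/ROI combinations",
              nrow(wcv_block))
  }
  if (is_longitudinal) {
    contrasts <- list(c(all_sessions[1], all_sessions[2]),
                      c(all_sessions[1], all_sessions[3]))
    combos <- table |> dplyr::distinct(.data$biomarker_name, .data$roi_name)
    anova_block <- purrr::pmap(combos, function(biomarker_name, roi_name) {
      sub <- dplyr::filter(table, .data$biomarker_name == !!biomarker_name,
                           .data$roi_name == !!roi_name)
      res <- tryCatch(rm_anova(sub, contrasts = contrasts),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      list(biomarker = biomarker_name, roi = roi_name, result = res)
    })
    anova_block <- purrr::compact(anova_block)
    log_stage("stats", "rm-ANOVA block: %d biomarker/ROI models",
              length(anova_block))
  }
  pair_tbl <- table |>
    dplyr::filter(.data$biomarker_name %in% rmcorr_pair) |>
    tidyr::pivot_wider(names_from = "biomarker_name", values_from = "value")
  if (all(rmcorr_pair %in% names(pair_tbl))) {
    rmcorr_block <- tryCatch(
      rm_correlation(pair_tbl, subject = "subject_id",
                     x = rmcorr_pair[1], y = rmcorr_pair[2]),
      error = function(e) NULL)
  }
  report <- list(
    design = list(is_retest = is_retest, is_longitudinal = is_longitudinal,
                  sessions = all_sessions),
    wcv = wcv_block,
    anova = lapply(anova_block, function(x) {
      c(list(biomarker = x$biomarker, roi = x$roi), tidy(x$result))
    }),
    rmcorr = if (!is.null(rmcorr_block)) tidy(rmcorr_block))
  jsonlite::write_json(report, file.path(config$out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  flat <- dplyr::bind_rows(
    if (!is.null(wcv_block) && nrow(wcv_block)) {
      wcv_block |>
        dplyr::transmute(block = "wcv", biomarker = .data$biomarker_name,
                         roi = .data$roi_name, term = "wcv_percent",
                         statistic = .data$wcv_percent, p.value = NA_real_,
                         p.bonferroni = NA_real_)
    },
    dplyr::bind_rows(lapply(anova_block, function(x) {
      tidy(x$result) |>
        dplyr::transmute(block = "rm_anova", biomarker = x$biomarker,
                         roi = x$roi, term = .data$term,
                         statistic = .data$statistic, p.value = .data$p.value,
                         p.bonferroni = .data$p.bonferroni)
    })),
    if (!is.null(rmcorr_block) && rmcorr_block$valid) {
      tibble::tibble(block = "rm_correlation",
                     biomarker = paste(rmcorr_pair, collapse = "~"),
                     roi = "all", term = "r", statistic = rmcorr_block$r,
                     p.value = rmcorr_block$p, p.bonferroni = NA_real_)
    })
  readr::write_csv(flat, file.path(config$out_dir, "stats_report.csv"))
  write_manifest(config, "stats",
                 inputs = file.path(config$out_dir, "biomarkers.csv"))
  invisible(list(wcv = wcv_block, anova = anova_block,
                 rmcorr = rmcorr_block, flat = flat))
}
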