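test_that("noiseless phantoms equal the forward model to 64-bit precision", {
  spec <- phantom_spec("two_region", noise_model = "none", seed = 1,
                       dim = c(6, 6, 2))
  ph <- generate_phantom(spec)
  b <- ph$dwi$scheme$bvalues
  tissue_sig <- noiseless_ivim(0.19, 1.3, 30)
  fluid_sig <- noiseless_ivim(0, 3.0, 30)
  for (v in which(ph$mask$labels == 1L)[1:5]) {
    idx <- arrayInd(v, dim(ph$mask$labels))
    expect_identical(ph$dwi$signal[idx[1], idx[2], idx[3], ], tissue_sig)
  }
  v <- which(ph$mask$labels == 2L)[1]
  idx <- arrayInd(v, dim(ph$mask$labels))
  expect_identical(ph$dwi$signal[idx[1], idx[2], idx[3], ], fluid_sig)
  # truth sidecar consistent with the spec on every voxel
  expect_true(all(ph$truth$D[ph$mask$labels == 1L] == 1.3))
  expect_true(all(ph$truth$f[ph$mask$labels == 2L] == 0))
})

test_that("generation is bitwise deterministic given the seed", {
  spec <- phantom_spec("pelvis_toy", snr_b0 = 30, noise_model = "rician",
                       seed = 77, dim = c(10, 10, 2))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$dwi$signal, b$dwi$signal)
  spec2 <- phantom_spec("pelvis_toy", snr_b0 = 30, noise_model = "rician",
                        seed = 78, dim = c(10, 10, 2))
  expect_false(identical(generate_phantom(spec2)$dwi$signal, a$dwi$signal))
})

test_that("gaussian noise honours the SNR contract", {
  geom <- array(1L, c(50, 50, 4))   # 10,000 voxels of one class
  cls <- list(tissue_class("tissue", f = 0.19, D = 1.3, Dstar = 30, label = 1))
  spec <- phantom_spec(geom, cls, snr_b0 = 50, noise_model = "gaussian",
                       seed = 5)
  ph <- generate_phantom(spec)
  resid_b0 <- ph$dwi$signal[, , , 1] - 1  # S0 = 1 at b = 0
  expect_lt(abs(sd(resid_b0) - 1 / 50) / (1 / 50), 0.03)
  expect_lt(abs(mean(resid_b0)), 3 * (1 / 50) / sqrt(10000))
})

test_that("rician magnitude bias is negligible at SNR >= 50", {
  geom <- array(1L, c(50, 50, 4))
  cls <- list(tissue_class("tissue", f = 0.19, D = 1.3, Dstar = 30, label = 1))
  spec <- phantom_spec(geom, cls, snr_b0 = 50, noise_model = "rician",
                       seed = 6)
  ph <- generate_phantom(spec)
  bias <- mean(ph$dwi$signal[, , , 1]) - 1
  expect_lt(abs(bias), 0.01)   # < 1% of S0
})

test_that("a geometry label without a class is a hard error", {
  geom <- array(1L, c(4, 4, 1)); geom[1, 1, 1] <- 9L
  cls <- list(tissue_class("tissue", f = 0.1, D = 1, Dstar = 20, label = 1))
  expect_error(phantom_spec(geom, cls), "without a tissue class")
})

test_that("test-retest cohorts have distinct derived seeds and exact chain identity at cv 0", {
  spec <- phantom_spec("two_region", noise_model = "none", seed = 9,
                       dim = c(6, 6, 1))
  cohort <- make_test_retest(spec, n_subjects = 6, between_session_cv = 0)
  expect_equal(nrow(cohort), 12)
  # cv = 0 and no noise: the two sessions of a subject are identical
  s1 <- cohort$phantom[[1]]$dwi$signal
  s2 <- cohort$phantom[[2]]$dwi$signal
  expect_identical(s1, s2)
  # with noise, derived seeds differ across subjects and sessions
  spec_n <- phantom_spec("two_region", snr_b0 = 50, noise_model = "gaussian",
                         seed = 9, dim = c(6, 6, 1))
  cn <- make_test_retest(spec_n, n_subjects = 2, between_session_cv = 0)
  sigs <- lapply(cn$phantom, function(p) p$dwi$signal)
  expect_false(identical(sigs[[1]], sigs[[2]]))
  expect_false(identical(sigs[[1]], sigs[[3]]))
})

test_that("session jitter of known CV propagates to the fitted wCV of D", {
  spec <- phantom_spec("two_region", noise_model = "none", seed = 101,
                       dim = c(6, 6, 1))
  cohort <- make_test_retest(spec, n_subjects = 40, between_session_cv = 0.08)
  rows <- purrr::pmap(cohort, function(subject_id, session, phantom, classes) {
    maps <- fit_dwi_volume(phantom$dwi)
    summarize_all_rois(maps, phantom$mask) |>
      dplyr::filter(roi_name == "tissue") |>
      dplyr::mutate(subject_id = subject_id, group = "healthy",
                    session = session)
  })
  tbl <- build_biomarker_table(dplyr::bind_rows(rows))
  res <- wcv(tbl, "D", "tissue")
  expect_lt(abs(res$wcv - 8), 1)
})

test_that("longitudinal series scale tumour D and shrink its volume", {
  geom <- array(2L, c(12, 12, 4))
  geom[3:12, 3:12, ] <- 3L   # 10 x 10 x 4 tumour
  cls <- list(tissue_class("tissue", f = 0.19, D = 1.3, Dstar = 30, label = 2),
              tissue_class("tumour", f = 0.10, D = 1.0, Dstar = 20, label = 3))
  spec <- phantom_spec(geom, cls, noise_model = "none", seed = 15)
  series <- make_longitudinal(spec, n_subjects = 1,
                              d_multipliers = c(1, 1.15, 1.15),
                              erode_steps = c(0L, 1L, 2L),
                              between_subject_cv = 0)
  expect_equal(series$session, c("baseline", "week3", "week5"))
  n_vox <- vapply(series$phantom, function(p) sum(p$mask$labels == 3L),
                  numeric(1))
  expect_true(all(diff(n_vox) < 0))  # strictly decreasing tumour volume
  # noiseless chain: fitted median D ratio week3 / baseline = 1.15 within 2%
  med_D <- vapply(series$phantom[1:2], function(p) {
    maps <- fit_dwi_volume(p$dwi, mask = p$mask)
    summarize_roi(maps, p$mask, 3L)$median_D
  }, numeric(1))
  expect_lt(abs(med_D[2] / med_D[1] - 1.15), 0.02 * 1.15)
  # identical multipliers and no erosion give identical-truth visits
  s2 <- make_longitudinal(spec, 1, d_multipliers = c(1, 1, 1),
                          erode_steps = c(0L, 0L, 0L),
                          between_subject_cv = 0)
  expect_identical(s2$phantom[[1]]$truth, s2$phantom[[2]]$truth)
  # erosion emptying the region is a hard error
  tiny <- array(2L, c(4, 4, 1)); tiny[2:3, 2:3, 1] <- 3L
  spec_tiny <- phantom_spec(tiny, cls, noise_model = "none", seed = 16)
  expect_error(make_longitudinal(spec_tiny, 1, erode_steps = c(0L, 1L, 2L),
                                 between_subject_cv = 0),
               "emptied")
})
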