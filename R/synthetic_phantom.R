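# Deterministic multi-tissue digital phantoms emulating a multi-b-value
# pelvic DW acquisition: per-class bi-exponential truth, Gaussian or Rician
# noise at a prescribed b = 0 SNR, test-retest and longitudinal cohorts.

#' A tissue class of a digital phantom
#'
#' @param name Class name (e.g. `"fluid"`, `"tissue"`, `"tumour"`).
#' @param S0,f,D,Dstar Ground-truth IVIM parameters ([ivim_params()]
#'   convention; `f = 0` gives a mono-exponential class whose `Dstar` is
#'   unused).
#' @param label Integer label of this class in the geometry map.
#' @return A `tissue_class`.
#' @export
tissue_class <- function(name, S0 = 1, f, D, Dstar = 30, label) {
  stopifnot(is.character(name), S0 > 0, f >= 0, f < 1, D > 0,
            label == round(label), label > 0)
  if (f > 0 && Dstar <= D) stop("Dstar must exceed D when f > 0")
  structure(list(name = name, S0 = S0, f = f, D = D, Dstar = Dstar,
                 label = as.integer(label)),
            class = "tissue_class")
}

# Geometry presets. "two_region": left/right halves, labels 1 (tissue) and
# 2 (fluid). "pelvis_toy": fluid pocket, normal tissue background, tumour
# block.
phantom_geometry <- function(preset, dim = c(16, 16, 2)) {
  g <- array(0L, dim)
  if (preset == "two_region") {
    half <- floor(dim[1] / 2)
    g[seq_len(half), , ] <- 1L
    g[(half + 1):dim[1], , ] <- 2L
  } else if (preset == "pelvis_toy") {
    g[] <- 2L                                      # normal tissue background
    fl <- seq_len(max(2, floor(dim[1] / 4)))
    g[fl, fl, ] <- 1L                              # fluid pocket
    tu_i <- (dim[1] - max(3, floor(dim[1] / 3)) + 1):dim[1]
    tu_j <- (dim[2] - max(3, floor(dim[2] / 3)) + 1):dim[2]
    g[tu_i, tu_j, ] <- 3L                          # tumour block
  } else {
    stop(sprintf("unknown geometry preset '%s'", preset))
  }
  g
}

default_classes <- function(preset) {
  if (preset == "two_region") {
    list(tissue_class("tissue", f = 0.19, D = 1.3, Dstar = 30, label = 1),
         tissue_class("fluid", f = 0, D = 3.0, label = 2))
  } else {
    # tumour values are plausible configurable stand-ins, not literature
    # constants; fluid and normal tissue carry the package defaults
    list(tissue_class("fluid", f = 0, D = 3.0, label = 1),
         tissue_class("tissue", f = 0.19, D = 1.3, Dstar = 30, label = 2),
         tissue_class("tumour", f = 0.10, D = 1.0, Dstar = 20, label = 3))
  }
}

#' Specification of a digital DW phantom
#'
#' @param geometry A 3D integer label array, or a preset name
#'   (`"two_region"`, `"pelvis_toy"`).
#' @param classes List of [tissue_class()] objects covering every non-zero
#'   geometry label; `NULL` takes the preset defaults.
#' @param scheme An [acquisition_scheme()]; default the 10-b-value scheme.
#' @param snr_b0 Signal-to-noise ratio at b = 0 relative to the largest
#'   class S0; the noise standard deviation is `max(S0) / snr_b0`.
#' @param noise_model `"gaussian"`, `"rician"`, or `"none"`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param dim Grid dimensions used when `geometry` is a preset name.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(geometry = "two_region", classes = NULL,
                         scheme = default_scheme(), snr_b0 = 50,
                         noise_model = c("gaussian", "rician", "none"),
                         seed = 1L, dim = c(16, 16, 2)) {
  noise_model <- match.arg(noise_model)
  if (is.character(geometry)) {
    if (is.null(classes)) classes <- default_classes(geometry)
    geometry <- phantom_geometry(geometry, dim)
  }
  stopifnot(length(dim(geometry)) == 3, !is.null(classes))
  labs <- setdiff(unique(as.vector(geometry)), 0L)
  have <- vapply(classes, function(cl) cl$label, integer(1))
  if (!all(labs %in% have)) {
    stop("geometry labels without a tissue class: ",
         paste(setdiff(labs, have), collapse = ", "))
  }
  if (noise_model != "none" && !(is.numeric(snr_b0) && snr_b0 > 0)) {
    stop("snr_b0 must be > 0 unless noise_model = 'none'")
  }
  structure(list(geometry = geometry, classes = classes, scheme = scheme,
                 snr_b0 = snr_b0, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic sub-seed derivation: keeps every derived seed in [0, 2^31).
derive_seed <- function(master, ...) {
  ids <- c(master, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Generate a digital DW phantom
#'
#' The noiseless signal is the bi-exponential forward model per tissue
#' class. Gaussian noise adds `Normal(0, sigma)` with
#' `sigma = max(S0) / snr_b0`; Rician noise takes the magnitude
#' `sqrt((S + n1)^2 + n2^2)` with independent `Normal(0, sigma)` channels,
#' the magnitude-MRI noise law. Generation is bitwise deterministic given
#' the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `dwi` (a `dwi_volume`), `mask` (an `roi_mask` of the
#'   class geometry), and `truth` (per-voxel S0, f, D, Dstar arrays plus
#'   the class-label map).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  d <- dim(g)
  b <- spec$scheme$bvalues
  n_b <- length(b)
  truth <- list(S0 = array(NA_real_, d), f = array(NA_real_, d),
                D = array(NA_real_, d), Dstar = array(NA_real_, d),
                labels = g)
  signal <- array(0, c(d, n_b))
  flat <- matrix(signal, prod(d), n_b)
  for (cl in spec$classes) {
    idx <- which(g == cl$label)
    if (!length(idx)) next
    truth$S0[idx] <- cl$S0; truth$f[idx] <- cl$f
    truth$D[idx] <- cl$D; truth$Dstar[idx] <- cl$Dstar
    flat[idx, ] <- matrix(ivim_signal_raw(cl$S0, cl$f, cl$D, cl$Dstar, b),
                          length(idx), n_b, byrow = TRUE)
  }
  if (spec$noise_model != "none") {
    s0_ref <- max(vapply(spec$classes, function(cl) cl$S0, numeric(1)))
    sigma <- s0_ref / spec$snr_b0
    nz <- which(g != 0L)
    withr_seed <- spec$seed
    old <- globalenv()$.Random.seed
    set.seed(withr_seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    if (spec$noise_model == "gaussian") {
      flat[nz, ] <- flat[nz, ] + matrix(stats::rnorm(length(nz) * n_b, 0, sigma),
                                        length(nz), n_b)
    } else {
      n1 <- matrix(stats::rnorm(length(nz) * n_b, 0, sigma), length(nz), n_b)
      n2 <- matrix(stats::rnorm(length(nz) * n_b, 0, sigma), length(nz), n_b)
      flat[nz, ] <- sqrt((flat[nz, ] + n1)^2 + n2^2)
    }
  }
  signal <- array(flat, c(d, n_b))
  names_map <- stats::setNames(
    as.list(vapply(spec$classes, function(cl) cl$name, character(1))),
    vapply(spec$classes, function(cl) as.character(cl$label), character(1)))
  list(dwi = dwi_volume(signal, spec$scheme, voxel_size = c(2.9, 2.9, 6.0)),
       mask = roi_mask(g, names_map),
       truth = truth)
}

jitter_classes <- function(classes, cv, d_ceiling = 4) {
  lapply(classes, function(cl) {
    repeat {
      f_j <- if (cl$f > 0) cl$f * (1 + stats::rnorm(1, 0, cv)) else 0
      D_j <- cl$D * (1 + stats::rnorm(1, 0, cv))
      Ds_j <- cl$Dstar * (1 + stats::rnorm(1, 0, cv))
      ok <- D_j > 0 && D_j <= d_ceiling && f_j >= 0 && f_j < 1 &&
        (f_j == 0 || Ds_j > D_j)
      if (ok) break
    }
    tissue_class(cl$name, S0 = cl$S0, f = f_j, D = D_j, Dstar = Ds_j,
                 label = cl$label)
  })
}

#' Generate a test-retest phantom cohort
#'
#' Each subject's session-level true parameters are drawn as
#' `truth * (1 + Normal(0, cv))` (applied to f, D and D*), emulating
#' between-session physiological variation; noise seeds derive
#' deterministically from (master seed, subject, session).
#'
#' @param spec A [phantom_spec()] carrying the cohort-level truth and seed.
#' @param n_subjects Number of subjects.
#' @param between_session_cv Coefficient of variation of the
#'   between-session parameter jitter (>= 0).
#' @param n_sessions Sessions per subject (default 2).
#' @return A tibble with columns `subject_id`, `session`, `phantom`
#'   (list-column of [generate_phantom()] outputs) and `classes`
#'   (list-column of the jittered per-session truth).
#' @export
make_test_retest <- function(spec, n_subjects, between_session_cv,
                             n_sessions = 2L) {
  stopifnot(inherits(spec, "phantom_spec"), between_session_cv >= 0,
            n_subjects >= 1, n_sessions >= 2)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (v in seq_len(n_sessions)) {
      sub_seed <- derive_seed(spec$seed, s, v)
      cls <- if (between_session_cv > 0) {
        old <- globalenv()$.Random.seed
        set.seed(derive_seed(sub_seed, 7L))
        cl <- jitter_classes(spec$classes, between_session_cv)
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
        cl
      } else spec$classes
      sp <- spec
      sp$classes <- cls
      sp$seed <- sub_seed
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sprintf("sub%02d", s),
        session = sprintf("session%d", v),
        phantom = list(generate_phantom(sp)),
        classes = list(cls))
    }
  }
  dplyr::bind_rows(rows)
}

# 6-neighbour binary erosion of a labelled region: a voxel keeps the label
# only if all face neighbours share it. Neighbours beyond the grid edge are
# treated as matching (replicated border), so only interfaces with other
# labels erode.
erode_label <- function(labels, label) {
  d <- dim(labels)
  inside <- labels == label
  keep <- inside
  shift_ok <- function(arr, ax, by) {
    out <- array(TRUE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    rng <- seq_len(d[ax] - abs(by))
    idx_dst[[ax]] <- if (by > 0) rng + by else rng
    idx_src[[ax]] <- if (by > 0) rng else rng + abs(by)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    if (d[ax] == 1) next  # degenerate axis: no erosion along it
    for (by in c(-1, 1)) keep <- keep & shift_ok(inside, ax, by)
  }
  out <- labels
  out[inside & !keep] <- 0L
  out
}

#' Generate a longitudinal (baseline / week 3 / week 5) phantom series
#'
#' Emulates a treatment-response scenario: the tumour class's tissue
#' diffusion coefficient is scaled per timepoint and the tumour region is
#' eroded to shrink its volume, with truth sidecars per visit.
#'
#' @param spec A [phantom_spec()] whose classes include `tumour_label`.
#' @param n_subjects Number of subjects.
#' @param d_multipliers Length-3 positive multipliers on tumour D, one per
#'   timepoint (default `c(1, 1.15, 1.15)`, a 15 percent on-treatment
#'   increase).
#' @param erode_steps Length-3 cumulative erosion steps per timepoint
#'   (default `c(0, 1, 2)` one-voxel layers).
#' @param tumour_label Geometry label of the tumour class (default 3).
#' @param timepoints Timepoint labels.
#' @param between_subject_cv Subject-level truth jitter CV (default 0.05).
#' @return A tibble with `subject_id`, `session` (timepoint), `phantom`
#'   and `classes` list-columns.
#' @export
make_longitudinal <- function(spec, n_subjects,
                              d_multipliers = c(1, 1.15, 1.15),
                              erode_steps = c(0L, 1L, 2L),
                              tumour_label = 3L,
                              timepoints = c("baseline", "week3", "week5"),
                              between_subject_cv = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"), length(d_multipliers) == 3,
            all(d_multipliers > 0), length(timepoints) == 3,
            length(erode_steps) == 3)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    base_cls <- if (between_subject_cv > 0) {
      old <- globalenv()$.Random.seed
      set.seed(derive_seed(spec$seed, s, 991L))
      cl <- jitter_classes(spec$classes, between_subject_cv)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
      cl
    } else spec$classes
    for (v in seq_along(timepoints)) {
      cls <- lapply(base_cls, function(cl) {
        if (cl$label == tumour_label) {
          D_new <- min(cl$D * d_multipliers[v], 4 - 1e-9)
          tissue_class(cl$name, S0 = cl$S0, f = cl$f, D = D_new,
                       Dstar = max(cl$Dstar, D_new + 1), label = cl$label)
        } else cl
      })
      geom <- spec$geometry
      if (erode_steps[v] > 0) {
        for (e in seq_len(erode_steps[v])) geom <- erode_label(geom, tumour_label)
      }
      if (!any(geom == tumour_label)) {
        stop("erosion emptied the tumour region")
      }
      sp <- spec
      sp$geometry <- geom
      sp$classes <- cls
      sp$seed <- derive_seed(spec$seed, s, 100L + v)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sprintf("pat%02d", s),
        session = timepoints[v],
        phantom = list(generate_phantom(sp)),
        classes = list(cls))
    }
  }
  dplyr::bind_rows(rows)
}
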