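# On-disk contract: NIfTI-1 volumes (Analyze 7.5 readable through the same
# reader), FSL-style .bval text files, and long-format biomarker CSVs.

#' Acquisition scheme: the ordered b-values of a DW protocol
#'
#' @param bvalues Numeric vector of diffusion weightings, s/mm^2. Stored
#'   sorted ascending; must contain at least 4 distinct values (the minimum
#'   for the IVIM fit to be attempted) and at most one b = 0 entry.
#' @param n_averages Positive integer, number of scanner-side signal
#'   averages. Metadata only; it does not enter any fit.
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvalues, n_averages = 1L) {
  stopifnot(is.numeric(bvalues), length(bvalues) >= 1)
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop("all b-values must be finite and >= 0")
  }
  if (!is.numeric(n_averages) || length(n_averages) != 1 || n_averages < 1) {
    stop("n_averages must be a positive integer")
  }
  b <- sort(bvalues)
  if (anyDuplicated(b)) stop("b-values must be distinct after sorting (average duplicate volumes on load)")
  if (length(b) < 4) stop("at least 4 distinct b-values are required")
  structure(list(bvalues = as.numeric(b), n_averages = as.integer(n_averages)),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x$bvalues), "b-values [s/mm^2]:",
      paste(x$bvalues, collapse = ", "),
      sprintf("(%d averages)\n", x$n_averages))
  invisible(x)
}

#' The 10-b-value pelvic DW protocol used throughout the package examples
#'
#' b = 0, 20, 40, 60, 80, 100, 150, 300, 500, 800 s/mm^2 with 4 averages.
#'
#' @return An [acquisition_scheme()].
#' @export
default_scheme <- function() {
  acquisition_scheme(c(0, 20, 40, 60, 80, 100, 150, 300, 500, 800),
                     n_averages = 4L)
}

new_dwi_volume <- function(signal, scheme, voxel_size, affine) {
  stopifnot(length(dim(signal)) == 4)
  if (dim(signal)[4] != length(scheme$bvalues)) {
    stop(sprintf("4th dimension (%d) does not match number of b-values (%d)",
                 dim(signal)[4], length(scheme$bvalues)))
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths in mm")
  }
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "dwi_volume")
}

#' Construct a 4D diffusion-weighted volume in memory
#'
#' @param signal 4D non-negative array indexed (x, y, z, b-index).
#' @param scheme An [acquisition_scheme()]; its length must equal the 4th
#'   dimension of `signal`.
#' @param voxel_size Voxel edge lengths, mm (length 3).
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a
#'   scaling by `voxel_size`.
#' @return A `dwi_volume` object.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  new_dwi_volume(signal, scheme, voxel_size, affine)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DW volume %d x %d x %d x %d, voxels %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  print(x$scheme)
  invisible(x)
}

# Build a writable NIfTI object from a bare array, attaching voxel size via
# the pixdim attribute (internal niftiImage objects reject pixdim<-).
make_nifti <- function(arr, voxel_size = NULL, datatype = "auto") {
  arr <- array(as.vector(arr), dim(arr))
  if (!is.null(voxel_size)) attr(arr, "pixdim") <- voxel_size
  RNifti::asNifti(arr, datatype = datatype)
}

read_bvals <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop(sprintf("negative or non-finite b-value in '%s'", path))
  }
  vals
}

#' Read a 4D DW volume and its b-value table
#'
#' Reads a NIfTI-1 (or Analyze 7.5) 4D image and an FSL-style whitespace-
#' separated b-value file (one entry per 4th-dimension volume). Volumes are
#' re-ordered so b-values ascend; volumes sharing a b-value (most commonly
#' repeated b = 0 acquisitions) are arithmetically averaged, so the returned
#' scheme has one sample per distinct b.
#'
#' @param volume_path Path to the 4D image (.nii, .nii.gz, or .hdr/.img).
#' @param bval_path Path to the b-value text file.
#' @param n_averages Scanner-side averages to record in the scheme metadata.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(volume_path, bval_path, n_averages = 1L) {
  img <- RNifti::readNifti(volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4) stop("expected a 4D image")
  bvals <- read_bvals(bval_path)
  if (length(bvals) != dim(arr)[4]) {
    stop(sprintf("b-value count (%d) does not match 4th image dimension (%d)",
                 length(bvals), dim(arr)[4]))
  }
  ub <- sort(unique(bvals))
  d <- dim(arr)
  out <- array(0, c(d[1:3], length(ub)))
  for (i in seq_along(ub)) {
    idx <- which(bvals == ub[i])
    sl <- arr[, , , idx, drop = FALSE]
    out[, , , i] <- rowMeans(array(sl, c(prod(d[1:3]), length(idx))),
                             dims = 1) |> array(d[1:3])
  }
  pd <- RNifti::pixdim(img)
  vx <- if (length(pd) >= 3) pd[1:3] else c(1, 1, 1)
  vx[vx <= 0] <- 1
  affine <- tryCatch(structure(RNifti::xform(img), class = NULL),
                     error = function(e) diag(c(vx, 1)))
  new_dwi_volume(out, acquisition_scheme(ub, n_averages), vx, affine)
}

#' Write a 4D DW volume and its b-value table
#'
#' Inverse of [read_dwi()]: writes the signal as a NIfTI-1 file and the
#' b-values as a single-line whitespace-separated text file.
#'
#' @param dwi A `dwi_volume`.
#' @param volume_path Output image path (.nii or .nii.gz).
#' @param bval_path Output b-value file path.
#' @return Invisibly, the two paths.
#' @export
write_dwi <- function(dwi, volume_path, bval_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- make_nifti(dwi$signal, voxel_size = dwi$voxel_size)
  RNifti::writeNifti(img, volume_path)
  writeLines(paste(dwi$scheme$bvalues, collapse = " "), bval_path)
  invisible(c(volume_path, bval_path))
}

#' Construct an ROI label mask
#'
#' @param labels 3D integer array; 0 is background.
#' @param label_names Named character vector or list mapping label integers
#'   (as names) to ROI names, e.g. `c("1" = "cervix", "2" = "tumour")`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, label_names = NULL) {
  stopifnot(length(dim(labels)) == 3)
  if (any(labels != round(labels), na.rm = TRUE)) {
    stop("mask must be integer-valued")
  }
  labels <- array(as.integer(round(labels)), dim(labels))
  structure(list(labels = labels, label_names = label_names),
            class = "roi_mask")
}

#' Read an ROI mask on the grid of a reference volume
#'
#' @param path Path to an integer-valued NIfTI/Analyze mask.
#' @param reference The `dwi_volume` whose grid the mask must share.
#' @param label_names Optional label-to-name map, see [roi_mask()].
#' @return An `roi_mask`.
#' @export
read_mask <- function(path, reference, label_names = NULL) {
  stopifnot(inherits(reference, "dwi_volume"))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
  # trailing singleton dimensions are dropped by some writers; restore them
  while (length(dim(arr)) < 3) dim(arr) <- c(dim(arr), 1L)
  ref_dim <- dim(reference$signal)[1:3]
  if (length(dim(arr)) != 3 || !all(dim(arr) == ref_dim)) {
    stop(sprintf("mask grid (%s) does not match reference grid (%s)",
                 paste(dim(arr), collapse = "x"),
                 paste(ref_dim, collapse = "x")))
  }
  if (any(abs(arr - round(arr)) > 1e-6)) stop("mask must be integer-valued")
  roi_mask(round(arr), label_names)
}

#' Write an ROI mask
#'
#' @param mask An `roi_mask`.
#' @param path Output path.
#' @param reference Optional `dwi_volume` supplying voxel size.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- make_nifti(mask$labels, datatype = "int16",
                    voxel_size = if (!is.null(reference)) reference$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write parameter and preference maps as NIfTI files
#'
#' Each named 3D map is written as one NIfTI file carrying the reference
#' volume's voxel size. A map named `"preference"` is written with integer
#' codes (0 = invalid, 1 = ADC preferred, 2 = IVIM preferred); all other
#' maps are written as 32-bit float.
#'
#' @param maps Named list of 3D arrays on the reference grid.
#' @param reference The `dwi_volume` defining the grid.
#' @param out_dir Output directory (created if missing).
#' @return A tibble manifest with one row per map: name, file, and the
#'   number of non-finite voxels (`n_nonfinite`, flagged when > 0).
#' @export
write_maps <- function(maps, reference, out_dir) {
  stopifnot(inherits(reference, "dwi_volume"), is.list(maps),
            !is.null(names(maps)), all(nzchar(names(maps))))
  ref_dim <- dim(reference$signal)[1:3]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- purrr::imap(maps, function(m, nm) {
    if (length(dim(m)) != 3 || !all(dim(m) == ref_dim)) {
      stop(sprintf("map '%s' grid does not match reference grid", nm))
    }
    dtype <- if (identical(nm, "preference")) "int16" else "float"
    img <- make_nifti(m, voxel_size = reference$voxel_size, datatype = dtype)
    path <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, path)
    tibble::tibble(name = nm, file = path,
                   n_nonfinite = sum(!is.finite(m)))
  })
  dplyr::bind_rows(rows)
}

biomarker_cols <- c("subject_id", "group", "session", "roi_name",
                    "biomarker_name", "value")

validate_biomarker_table <- function(tbl) {
  missing <- setdiff(biomarker_cols, names(tbl))
  if (length(missing)) {
    stop("biomarker table lacks columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(tbl$subject_id, tbl$session, tbl$roi_name, tbl$biomarker_name,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tbl[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate (subject, session, roi, biomarker) record: %s/%s/%s/%s",
      dup$subject_id, dup$session, dup$roi_name, dup$biomarker_name))
  }
  tibble::as_tibble(tbl[biomarker_cols])
}

#' Read a long-format biomarker table
#'
#' The CSV must carry the header
#' `subject_id,group,session,roi_name,biomarker_name,value`. Units are fixed
#' per biomarker: D, ADC_b0, ADC_b150, delta_ADC in um^2/ms; f and p_IVIM
#' dimensionless; volume in cm^3.
#'
#' @param path CSV path.
#' @return A tibble with one row per (subject, session, roi, biomarker);
#'   duplicate keys are rejected.
#' @export
read_biomarker_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           group = readr::col_character(),
                           session = readr::col_character(),
                           roi_name = readr::col_character(),
                           biomarker_name = readr::col_character(),
                           value = readr::col_double()))
  validate_biomarker_table(tbl)
}

#' Write a long-format biomarker table
#'
#' @param table Tibble with the biomarker-table columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_biomarker_table <- function(table, path) {
  tbl <- validate_biomarker_table(table)
  readr::write_csv(tbl, path)
  invisible(path)
}
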