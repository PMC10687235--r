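# Container I/O for slices, masks and cohort tables.

#' Write a slice or mask as NIfTI
#'
#' Stores a 2-D grid (HU slice or integer label mask) as a NIfTI file
#' with the pixel spacing in the header.  Requires the RNifti package.
#'
#' @param x A [ct_slice] or an integer mask matrix.
#' @param path Output .nii/.nii.gz path.
#' @param spacing Pixel spacing for plain matrices (ignored for
#'   `ct_slice`).
#' @return `path`, invisibly.
#' @export
write_slice_nifti <- function(x, path, spacing = c(1, 1)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  if (inherits(x, "ct_slice")) {
    spacing <- x$spacing
    x <- x$pixels
  }
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a slice from NIfTI
#'
#' @param path NIfTI file written by [write_slice_nifti].
#' @param as_mask Return the raw integer matrix (for label masks)
#'   instead of a [ct_slice].
#' @return A [ct_slice], or an integer matrix when `as_mask = TRUE`.
#' @export
read_slice_nifti <- function(path, as_mask = FALSE) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  img <- RNifti::readNifti(path)
  m <- matrix(as.integer(round(img)), nrow(img))
  if (as_mask) return(validate_tissue_mask(m))
  sp <- RNifti::pixdim(img)[1:2]
  ct_slice(m, sp)
}

#' Write an EMR cohort as three CSV tables
#'
#' The interchange layout: `encounters.csv` (patient_id, date),
#' `observations.csv` (patient_id, date, name, value) and `codes.csv`
#' (patient_id, date, system, code), plus `patients.csv` with
#' demographics and scan dates.
#'
#' @param records List of [patient_record] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_emr_csv <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id,
               scan_datetime = r$scan_datetime,
               birthdate = r$birthdate, sex = r$sex)))
  enc <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, date = r$encounters)))
  obs <- do.call(rbind, lapply(records, function(r)
    if (nrow(r$observations) > 0)
      cbind(patient_id = r$patient_id, r$observations) else NULL))
  cod <- do.call(rbind, lapply(records, function(r)
    if (nrow(r$codes) > 0)
      cbind(patient_id = r$patient_id, r$codes) else NULL))
  utils::write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(enc, file.path(dir, "encounters.csv"),
                   row.names = FALSE)
  utils::write.csv(obs, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(cod, file.path(dir, "codes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an EMR cohort from the three-CSV layout
#'
#' @param dir Directory written by [write_emr_csv].
#' @return List of [patient_record] objects.
#' @export
read_emr_csv <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE)
  enc <- utils::read.csv(file.path(dir, "encounters.csv"),
                         stringsAsFactors = FALSE)
  obs_path <- file.path(dir, "observations.csv")
  cod_path <- file.path(dir, "codes.csv")
  obs <- if (file.exists(obs_path))
    utils::read.csv(obs_path, stringsAsFactors = FALSE) else NULL
  cod <- if (file.exists(cod_path))
    utils::read.csv(cod_path, stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(pat)), function(i) {
    pid <- pat$patient_id[i]
    o <- if (!is.null(obs) && nrow(obs) > 0)
      obs[obs$patient_id == pid, c("date", "name", "value"),
          drop = FALSE] else
      data.frame(date = character(), name = character(),
                 value = numeric())
    o$date <- as.Date(o$date)
    cd <- if (!is.null(cod) && nrow(cod) > 0)
      cod[cod$patient_id == pid, c("date", "system", "code"),
          drop = FALSE] else
      data.frame(date = character(), system = character(),
                 code = character())
    cd$date <- as.Date(cd$date)
    patient_record(patient_id = pid,
                   scan_datetime = as.Date(pat$scan_datetime[i]),
                   birthdate = as.Date(pat$birthdate[i]),
                   sex = pat$sex[i],
                   encounters = as.Date(enc$date[enc$patient_id == pid]),
                   observations = o, codes = cd)
  })
}

#' Write a cohort-saliency table as CSV
#'
#' @param x A `cohort_saliency`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_saliency_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort_saliency"))
  tab <- x$table
  tab$n <- x$n_images
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
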