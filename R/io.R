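#' Write an image matrix as a NIfTI-1 volume
#'
#' @param img Numeric matrix or array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixdim Voxel dimensions in mm (recycled to the array rank).
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(img, path, pixdim = c(1, 1, 1)) {
  arr <- as.array(img)
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- rep_len(pixdim, length(dim(arr)))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path File path.
#' @return Numeric array.
#' @export
read_nifti_map <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write a spectrum as CSV plus JSON sidecar
#'
#' Two-column-per-channel CSV (ppm, real, imag) and a sidecar JSON holding
#' echo time, water reference area, tissue fractions and frequency scale.
#'
#' @param spec An [mrs_spectrum()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  utils::write.csv(data.frame(ppm = spec$ppm, real = spec$real,
                              imag = spec$imag),
                   path, row.names = FALSE)
  jsonlite::write_json(list(te = spec$te,
                            water_reference_area = spec$water_reference_area,
                            tissue_fractions = spec$tissue_fractions,
                            hz_per_ppm = spec$hz_per_ppm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_csv()]
#'
#' @param path CSV path with `<path>.json` sidecar alongside.
#' @return An [mrs_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mrs_spectrum(d$ppm, d$real, d$imag, meta$te, meta$water_reference_area,
               meta$tissue_fractions, meta$hz_per_ppm)
}

#' Write a ground-truth sidecar JSON
#'
#' @param gt Ground-truth list (typically `attr(x, "ground_truth")`).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
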