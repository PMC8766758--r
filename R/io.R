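# Thin I/O layer over the standard formats: NIfTI volumes via RNifti,
# per-voxel fit tables as CSV/TSV, perimetry summaries as JSON.

#' Read / write volumes as NIfTI
#'
#' @param x 3D or 4D numeric array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   plain numeric array with a `voxel_size_mm` attribute.
#' @export
write_volume <- function(x, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep_len(voxel_size_mm, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write / read pRF fit tables
#'
#' Per-voxel fits are exchanged as plain CSV with the native voxel indices
#' and fitted parameters (`voxel, i, j, k, x0, y0, sigma, amplitude, r2,
#' reliable, ...`).
#'
#' @param fits A `prf_fits` data frame.
#' @param path CSV path.
#' @return `write_fits_csv` returns `path` invisibly; `read_fits_csv`
#'   returns the `prf_fits` data frame.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(as.data.frame(fits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits_csv
#' @export
read_fits_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("prf_fits", "data.frame")
  out
}

#' Perimetry summary as JSON
#'
#' Writes a compact JSON report: mean deviation and BCEA per eye plus the
#' scotoma hull vertices, the quantities a downstream residual-function
#' analysis needs.
#'
#' @param points Perimetry data frame (both eyes).
#' @param fixation Named list of fixation sample matrices per eye (optional).
#' @param normals Normative field.
#' @param path Output JSON path.
#' @return The summary list, invisibly.
#' @export
write_perimetry_summary <- function(points, fixation = NULL,
                                    normals = normative_field(), path) {
  eyes <- unique(points$eye)
  md <- lapply(eyes, function(e) {
    mean_deviation(points[points$eye == e, ], normals)
  })
  names(md) <- eyes
  hulls <- lapply(eyes, function(e) {
    h <- scotoma_hull(points[points$eye == e, ])
    if (h$empty) NULL else apply(h$vertices, 1, as.numeric, simplify = FALSE)
  })
  names(hulls) <- eyes
  out <- list(mean_deviation_db = md, hull_vertices = hulls)
  if (!is.null(fixation)) {
    out$bcea_deg2 <- lapply(fixation, function(s) bcea(s)$bcea)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out)
}
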