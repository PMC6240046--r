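#' NIfTI read/write helpers
#'
#' Thin wrappers around RNifti for the package's volume types: 4D float
#' series (scans x voxels matrices with a `grid` attribute), 3D statistic
#' or participation-coefficient maps, and integer label volumes.
#'
#' @param series Scans x voxels matrix with attribute `grid` (3D dims).
#' @param path Output `.nii`/`.nii.gz` path.
#' @param tr Repetition time stored in the header (seconds).
#' @return Writers return `path` invisibly.
#' @export
write_bold_nifti <- function(series, path, tr = NA_real_) {
  grid <- attr(series, "grid")
  stopifnot(!is.null(grid), length(grid) == 3)
  arr <- array(t(series), dim = c(grid, nrow(series)))
  img <- RNifti::asNifti(arr)
  if (is.finite(tr)) RNifti::pixdim(img)[4] <- tr
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  grid <- dim(arr)[1:3]
  n_scans <- dim(arr)[4]
  series <- t(matrix(arr, prod(grid), n_scans))
  attr(series, "grid") <- grid
  series
}

#' @rdname write_bold_nifti
#' @param map Numeric vector over voxels (linear order) or 3D array.
#' @param grid 3D dims when `map` is a vector.
#' @export
write_map_nifti <- function(map, path, grid = NULL) {
  if (is.null(dim(map))) {
    stopifnot(!is.null(grid), length(map) == prod(grid))
    map <- array(map, dim = grid)
  }
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_map_nifti <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' @rdname write_bold_nifti
#' @param labels Integer 3D label array.
#' @export
write_labels_nifti <- function(labels, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)),
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_labels_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.integer(round(arr)), dim = dim(arr))
}

#' Write / read a numeric matrix as TSV
#'
#' @param m Numeric matrix.
#' @param path TSV path.
#' @return `read_matrix_tsv` returns an unnamed numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
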