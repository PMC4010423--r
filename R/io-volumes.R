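#' @include utils.R
NULL

#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti. Integer masks round-trip bit-exactly; float
#' maps round-trip to better than 1e-6. The affine defaults to the identity
#' (voxel space): positions throughout the package are in voxel units.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param dimensions Expected number of dimensions (3 or 4), checked on read;
#'   `NULL` skips the check.
#' @return `readVolume()` returns a plain numeric array; `writeVolume()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(array(1:8, c(2, 2, 2)), f)
#' readVolume(f)[2, 2, 2]
#' @export
readVolume <- function(path, dimensions = NULL) {
  if (!file.exists(path)) stop("no such volume: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  if (!is.null(dimensions) && length(dim(a)) != dimensions)
    stop("volume ", path, " has ", length(dim(a)),
         " dimensions; expected ", dimensions)
  a
}

#' @rdname readVolume
#' @param x Numeric, integer or logical array (3-D or 4-D).
#' @param affine Optional 4 x 4 voxel-to-world matrix recorded in the header.
#' @export
writeVolume <- function(x, path, affine = NULL) {
  stopifnot(length(dim(x)) %in% c(3L, 4L))
  if (is.logical(x)) storage.mode(x) <- "integer"
  img <- RNifti::asNifti(x)
  if (!is.null(affine))
    RNifti::sform(img) <- structure(affine, code = 2L)
  dt <- if (is.integer(x)) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
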