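# Internal voxel-grid helpers. Voxel indices are 1-based integer triplets,
# voxel centers sit at integer coordinates, linear indices follow R array
# order (x fastest).

.lin <- function(vox, dims) {
  vox <- matrix(as.integer(vox), ncol = 3L)
  as.integer(vox[, 1L] + dims[1L] * ((vox[, 2L] - 1L) +
             dims[2L] * (vox[, 3L] - 1L)))
}

.coords <- function(lin, dims) {
  lin0 <- as.integer(lin) - 1L
  x <- lin0 %% dims[1L]
  y <- (lin0 %/% dims[1L]) %% dims[2L]
  z <- lin0 %/% (dims[1L] * dims[2L])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

.checkDims <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("grid dimensions must be three positive integers")
  dims
}

# logical array -> n x 3 voxel matrix
.maskVoxels <- function(mask) {
  w <- which(mask)
  if (length(w) == 0L)
    return(matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z"))))
  .coords(w, dim(mask))
}

# membership lookup table: logical vector over linear indices
.regionLookup <- function(region) {
  stopifnot(is(region, "Region"))
  lut <- logical(prod(region@dims))
  lut[.lin(region@voxels, region@dims)] <- TRUE
  lut
}

.zeroArray <- function(dims) array(0, dim = dims)

.stopifnotSameGrid <- function(a, b) {
  if (!identical(as.integer(a), as.integer(b)))
    stop("objects are defined on different voxel grids")
}
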