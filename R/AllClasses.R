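#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Tracking parameters
#'
#' Parameters of the FACT-style probabilistic propagation. The inner-product
#' threshold between consecutive step directions bounds the within-voxel
#' curvature: the default 0.5 admits turns of at most \eqn{\arccos(0.5) =
#' 60}{acos(0.5) = 60} degrees per step. Streamlines are propagated in both
#' directions from the seed voxel by default; the two half-tracks count as one
#' streamline.
#'
#' @slot innerProductThreshold Minimum inner product between consecutive unit
#'   step directions, in (0, 1].
#' @slot maxSteps Maximum number of steps per half-track; `NA` resolves to
#'   ten times the longest grid dimension at tracking time.
#' @slot rngSeed Integer root seed; every (voxel, stream) pair derives its own
#'   substream from it, so results are reproducible and cacheable.
#' @slot bidirectional Launch two half-tracks with opposite initial signs.
#'
#' @param innerProductThreshold,maxSteps,rngSeed,bidirectional See slots.
#' @return A `TrackingParams` object.
#' @examples
#' TrackingParams(rngSeed = 1)
#' @export TrackingParams
#' @exportClass TrackingParams
TrackingParams <- setClass("TrackingParams",
  representation(innerProductThreshold = "numeric", maxSteps = "integer",
                 rngSeed = "numeric", bidirectional = "logical"))

setValidity("TrackingParams", function(object) {
  t <- object@innerProductThreshold
  if (length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    return("innerProductThreshold must be a single value in (0, 1]")
  if (length(object@maxSteps) != 1L ||
      (!is.na(object@maxSteps) && object@maxSteps < 1L))
    return("maxSteps must be a single integer >= 1 (or NA)")
  if (length(object@rngSeed) != 1L || is.na(object@rngSeed))
    return("rngSeed must be a single number")
  if (length(object@bidirectional) != 1L || is.na(object@bidirectional))
    return("bidirectional must be TRUE or FALSE")
  TRUE
})

#' @rdname TrackingParams-class
#' @usage NULL
setMethod("initialize", "TrackingParams",
  function(.Object, innerProductThreshold = 0.5, maxSteps = NA_integer_,
           rngSeed = 1, bidirectional = TRUE, ...) {
    callNextMethod(.Object,
                   innerProductThreshold = as.numeric(innerProductThreshold),
                   maxSteps = as.integer(maxSteps),
                   rngSeed = as.numeric(rngSeed),
                   bidirectional = as.logical(bidirectional), ...)
  })

#' ICE-T parameters
#'
#' Parameters of the iterative seed-region-growing loop. `icetStreams` is the
#' number of streamlines emitted per seed voxel at each iteration (default 20),
#' `icetThreshold` the PICo level a voxel must reach to be appended to the
#' growing region (default 0.01), and `globalThreshold` the level applied to
#' the final Intra-Tract Confidence map (default 0.005). `maxIterations` is a
#' safety cap only; the loop normally stops when the region stops growing.
#'
#' @slot icetStreams Streamlines per seed voxel per iteration, >= 1.
#' @slot icetThreshold Per-iteration PICo threshold, in (0, 1].
#' @slot globalThreshold Threshold for the final confidence map, in (0, 1].
#' @slot maxIterations Iteration safety cap.
#'
#' @param icetStreams,icetThreshold,globalThreshold,maxIterations See slots.
#' @return An `ICETParams` object.
#' @examples
#' ICETParams(icetStreams = 20, icetThreshold = 0.01)
#' @export ICETParams
#' @exportClass ICETParams
ICETParams <- setClass("ICETParams",
  representation(icetStreams = "integer", icetThreshold = "numeric",
                 globalThreshold = "numeric", maxIterations = "integer"))

setValidity("ICETParams", function(object) {
  if (length(object@icetStreams) != 1L || is.na(object@icetStreams) ||
      object@icetStreams < 1L)
    return("icetStreams must be a single integer >= 1")
  t <- object@icetThreshold
  if (length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    return("icetThreshold must be in (0, 1]")
  g <- object@globalThreshold
  if (length(g) != 1L || is.na(g) || g <= 0 || g > 1)
    return("globalThreshold must be in (0, 1]")
  if (length(object@maxIterations) != 1L || is.na(object@maxIterations) ||
      object@maxIterations < 1L)
    return("maxIterations must be a single integer >= 1")
  TRUE
})

#' @rdname ICETParams-class
#' @usage NULL
setMethod("initialize", "ICETParams",
  function(.Object, icetStreams = 20L, icetThreshold = 0.01,
           globalThreshold = 0.005, maxIterations = 200L, ...) {
    callNextMethod(.Object, icetStreams = as.integer(icetStreams),
                   icetThreshold = as.numeric(icetThreshold),
                   globalThreshold = as.numeric(globalThreshold),
                   maxIterations = as.integer(maxIterations), ...)
  })

# ---------------------------------------------------------------------------
# Regions
# ---------------------------------------------------------------------------

#' Voxel region
#'
#' A set of voxels on a fixed grid: seed regions, waypoint regions, exclusion
#' masks and segmentation results are all `Region` objects. Voxel indices are
#' 1-based triplets; duplicates are removed on construction (set semantics).
#'
#' @slot voxels Integer matrix, one voxel index triplet per row.
#' @slot dims Grid dimensions (nx, ny, nz).
#'
#' @param voxels n x 3 matrix of voxel indices (or a vector of linear indices).
#' @param dims Grid dimensions.
#' @return A `Region` object.
#' @examples
#' Region(rbind(c(1, 1, 1), c(2, 1, 1)), dims = c(4, 4, 4))
#' @export Region
#' @exportClass Region
Region <- setClass("Region",
  representation(voxels = "matrix", dims = "integer"))

setValidity("Region", function(object) {
  v <- object@voxels
  d <- object@dims
  if (length(d) != 3L || any(d < 1L)) return("dims must be three positive integers")
  if (ncol(v) != 3L) return("voxels must have three columns")
  if (nrow(v) > 0L) {
    if (any(is.na(v))) return("voxel indices must not be NA")
    if (any(v < 1L) || any(v[, 1L] > d[1L]) || any(v[, 2L] > d[2L]) ||
        any(v[, 3L] > d[3L]))
      return("voxel indices out of grid bounds")
    if (anyDuplicated(.lin(v, d))) return("duplicate voxels in region")
  }
  TRUE
})

#' @rdname Region-class
#' @usage NULL
setMethod("initialize", "Region", function(.Object, voxels, dims, ...) {
  dims <- .checkDims(dims)
  if (is.null(dim(voxels))) {
    voxels <- if (length(voxels) == 0L)
      matrix(integer(0), ncol = 3L) else .coords(voxels, dims)
  }
  voxels <- matrix(as.integer(voxels), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(voxels) > 0L)
    voxels <- voxels[!duplicated(.lin(voxels, dims)), , drop = FALSE]
  callNextMethod(.Object, voxels = voxels, dims = dims, ...)
})

#' Convert a logical array to a Region, and back
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @return `regionFromMask()` returns a [Region]; `regionToMask()` a logical
#'   array of the region's grid dimensions.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
#' r <- regionFromMask(m)
#' all(regionToMask(r) == m)
#' @export
regionFromMask <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  Region(voxels = .maskVoxels(mask != 0), dims = dim(mask))
}

#' @rdname regionFromMask
#' @param region A [Region].
#' @export
regionToMask <- function(region) {
  stopifnot(is(region, "Region"))
  m <- array(FALSE, dim = region@dims)
  m[.lin(region@voxels, region@dims)] <- TRUE
  m
}

# ---------------------------------------------------------------------------
# Direction fields and phantoms
# ---------------------------------------------------------------------------

#' Fiber direction field
#'
#' A voxel grid carrying 0--2 unit fiber directions per voxel, each with an
#' angular dispersion (degrees). This is the uncertainty-ODF stand-in that the
#' probabilistic tracker samples: at every voxel visit the tracker perturbs the
#' chosen population direction by a half-normal angle with standard deviation
#' equal to the population's dispersion, about a uniformly random perpendicular
#' axis. Voxels inside the tissue mask but with zero populations terminate
#' streamlines (background tissue).
#'
#' @slot dims Grid dimensions (nx, ny, nz).
#' @slot npop Integer array: number of fiber populations per voxel (0, 1 or 2).
#' @slot dir1,dir2 4-D arrays (nx, ny, nz, 3): unit direction of populations
#'   1 and 2 (zero where absent).
#' @slot disp1,disp2 3-D arrays: angular dispersion in degrees.
#' @slot mask Logical array: tissue mask; populations are empty outside it.
#'
#' @param dims,npop,dir1,dir2,disp1,disp2,mask See slots; `dir2`/`disp2`
#'   default to zero arrays when every voxel has at most one population.
#' @return A `DirectionField` object.
#' @export DirectionField
#' @exportClass DirectionField
DirectionField <- setClass("DirectionField",
  representation(dims = "integer", npop = "array", dir1 = "array",
                 dir2 = "array", disp1 = "array", disp2 = "array",
                 mask = "array"))

setValidity("DirectionField", function(object) {
  d <- object@dims
  if (!identical(dim(object@npop), d)) return("npop has wrong dimensions")
  if (!identical(dim(object@mask), d)) return("mask has wrong dimensions")
  if (!identical(dim(object@dir1), c(d, 3L)) ||
      !identical(dim(object@dir2), c(d, 3L)))
    return("dir1/dir2 must have dimensions c(dims, 3)")
  if (!identical(dim(object@disp1), d) || !identical(dim(object@disp2), d))
    return("disp1/disp2 have wrong dimensions")
  if (any(object@npop < 0L) || any(object@npop > 2L))
    return("at most two fiber populations per voxel")
  if (any(object@npop[!object@mask] != 0L))
    return("populations must be empty outside the mask")
  if (any(object@disp1 < 0) || any(object@disp2 < 0) ||
      any(object@disp1 >= 90) || any(object@disp2 >= 90))
    return("dispersion must lie in [0, 90) degrees")
  n <- prod(d)
  dir1 <- matrix(object@dir1, n, 3L)
  has1 <- object@npop >= 1L
  if (any(abs(sqrt(rowSums(dir1^2))[has1] - 1) > 1e-9))
    return("population-1 directions must be unit vectors")
  dir2 <- matrix(object@dir2, n, 3L)
  has2 <- object@npop == 2L
  if (any(abs(sqrt(rowSums(dir2^2))[has2] - 1) > 1e-9))
    return("population-2 directions must be unit vectors")
  TRUE
})

#' @rdname DirectionField-class
#' @usage NULL
setMethod("initialize", "DirectionField",
  function(.Object, dims, npop, dir1, dir2 = NULL, disp1 = NULL, disp2 = NULL,
           mask = NULL, ...) {
    dims <- .checkDims(dims)
    if (is.null(dir2)) dir2 <- array(0, c(dims, 3L))
    if (is.null(disp1)) disp1 <- .zeroArray(dims)
    if (is.null(disp2)) disp2 <- .zeroArray(dims)
    if (is.null(mask)) mask <- array(TRUE, dims)
    storage.mode(npop) <- "integer"
    callNextMethod(.Object, dims = dims, npop = npop, dir1 = dir1,
                   dir2 = dir2, disp1 = disp1, disp2 = disp2,
                   mask = array(as.logical(mask), dims), ...)
  })

#' Synthetic fiber phantom
#'
#' A [DirectionField] together with its ground truth: one binary mask and one
#' ordered centerline per bundle, and named regions (at least a seed region)
#' for tracking experiments.
#'
#' @slot field The [DirectionField].
#' @slot bundleMasks Named list of logical arrays, one per bundle.
#' @slot centerlines Named list of ordered voxel-coordinate matrices.
#' @slot regions Named list of [Region] objects (contains at least "seed").
#'
#' @param field,bundleMasks,centerlines,regions See slots.
#' @return A `Phantom` object.
#' @seealso [makeStraightBundle()], [makeCrossingPhantom()],
#'   [makeBranchingPhantom()]
#' @export Phantom
#' @exportClass Phantom
Phantom <- setClass("Phantom",
  representation(field = "DirectionField", bundleMasks = "list",
                 centerlines = "list", regions = "list"))

setValidity("Phantom", function(object) {
  d <- object@field@dims
  for (nm in names(object@bundleMasks)) {
    m <- object@bundleMasks[[nm]]
    if (!identical(dim(m), d)) return(sprintf("bundle mask '%s' has wrong dims", nm))
    if (any(m & !object@field@mask))
      return(sprintf("bundle mask '%s' leaves the tissue mask", nm))
  }
  for (nm in names(object@centerlines)) {
    cl <- object@centerlines[[nm]]
    if (ncol(cl) != 3L) return("centerlines must be n x 3 matrices")
    bm <- object@bundleMasks[[nm]]
    if (!is.null(bm) && !all(bm[.lin(round(cl), d)]))
      return(sprintf("centerline '%s' leaves its bundle mask", nm))
  }
  if (!"seed" %in% names(object@regions)) return("phantom must carry a seed region")
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    if (!is(r, "Region")) return("regions must be Region objects")
    if (!identical(r@dims, d)) return(sprintf("region '%s' on wrong grid", nm))
  }
  # voxels belonging to >= 2 bundles must carry exactly two populations
  if (length(object@bundleMasks) >= 2L) {
    cnt <- Reduce(`+`, lapply(object@bundleMasks, function(m) m * 1L))
    if (any(object@field@npop[cnt >= 2L] != 2L))
      return("bundle-crossing voxels must carry exactly two populations")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Streamlines
# ---------------------------------------------------------------------------

#' A single streamline
#'
#' Ordered continuous 3-D positions (voxel units) plus the ordered voxel path,
#' the seed voxel and the termination status of the forward half-track. For
#' bidirectional tracking the reversed backward half precedes the forward half,
#' so points run end-to-end and the seed-voxel center appears once.
#'
#' @slot points m x 3 matrix of positions, voxel units.
#' @slot voxels m x 3 matrix of visited voxel indices (ordered, one per point).
#' @slot seedVoxel Voxel index triplet the streamline was launched from.
#' @slot status One of `"exited_mask"`, `"no_population"`, `"curvature_stop"`,
#'   `"max_steps"`.
#' @export
#' @exportClass Streamline
setClass("Streamline",
  representation(points = "matrix", voxels = "matrix",
                 seedVoxel = "integer", status = "character"))

.trackStatusLevels <- c("exited_mask", "no_population", "curvature_stop",
                        "max_steps")

#' Set of streamlines
#'
#' Holds the streamlines emitted from a seed region, together with the emitted
#' count `nEmitted` used as the PICo normalisation denominator. Waypoint and
#' exclusion filtering drop streamlines but never change `nEmitted`, so map
#' values always mean "fraction of emitted streamlines". A bidirectional
#' half-track pair counts as one streamline.
#'
#' Internally the voxel paths are stored as ordered linear-index vectors for
#' speed; `[[` materialises a [Streamline-class] object.
#'
#' @slot dims Grid dimensions.
#' @slot paths List of ordered voxel linear-index vectors.
#' @slot points List of m x 3 point matrices (may be empty when tracking was
#'   run without point storage).
#' @slot status Integer termination codes (see [Streamline-class]).
#' @slot seedVoxel Integer linear index of each streamline's seed voxel.
#' @slot streamId Integer per-voxel substream id of each streamline.
#' @slot nEmitted Number of streamlines emitted before any filtering.
#'
#' @param dims,paths,points,status,seedVoxel,streamId,nEmitted See slots.
#' @return A `StreamlineSet`.
#' @export StreamlineSet
#' @exportClass StreamlineSet
StreamlineSet <- setClass("StreamlineSet",
  representation(dims = "integer", paths = "list", points = "list",
                 status = "integer", seedVoxel = "integer",
                 streamId = "integer", nEmitted = "integer"))

setValidity("StreamlineSet", function(object) {
  n <- length(object@paths)
  if (length(object@status) != n || length(object@seedVoxel) != n ||
      length(object@streamId) != n)
    return("per-streamline slots must have equal length")
  if (length(object@points) && length(object@points) != n)
    return("points must be empty or parallel to paths")
  if (object@nEmitted < n)
    return("nEmitted must be >= the number of retained streamlines")
  if (n > 0L && (any(object@status < 1L) | any(object@status > 4L)))
    return("unknown termination status code")
  TRUE
})

# ---------------------------------------------------------------------------
# Maps
# ---------------------------------------------------------------------------

#' PICo connection-confidence map
#'
#' Per-voxel fraction of emitted streamlines whose voxelised path visited the
#' voxel, scaled to [0, 1]. Each streamline contributes at most once per voxel.
#'
#' @slot values Float array over the grid, in [0, 1].
#' @slot nEmitted The normalisation denominator (emitted streamline count).
#' @slot seed The [Region] streamlines were emitted from.
#'
#' @param values,nEmitted,seed See slots.
#' @return A `PICoMap`.
#' @export PICoMap
#' @exportClass PICoMap
PICoMap <- setClass("PICoMap",
  representation(values = "array", nEmitted = "integer", seed = "Region"))

setValidity("PICoMap", function(object) {
  if (object@nEmitted < 1L) return("nEmitted must be >= 1")
  v <- object@values
  if (any(v < 0) || any(v > 1)) return("map values must lie in [0, 1]")
  TRUE
})

#' Intra-Tract Confidence map
#'
#' The visitation map obtained by re-seeding tractography from the final grown
#' region ROI_I: each voxel's value reflects how well connected it is to all
#' other voxels of the segmented tract, rather than to the original seed.
#' Unlike a plain PICo map it admits a single global threshold because the
#' path-length-dependency decay has been removed by the region growing.
#'
#' @seealso [intraTractConfidence()], [segmentTract()]
#' @export IntraTractConfidenceMap
#' @exportClass IntraTractConfidenceMap
IntraTractConfidenceMap <- setClass("IntraTractConfidenceMap",
                                    contains = "PICoMap")

# ---------------------------------------------------------------------------
# ICE-T state and profiles
# ---------------------------------------------------------------------------

#' ICE-T iteration state
#'
#' Full history of an ICE-T run: the region after every iteration
#' (`roiHistory`), their sizes, whether the loop converged (the region stopped
#' growing) and the parameters used. The original seed is always contained in
#' every region of the history, and region sizes are non-decreasing.
#'
#' @slot roiHistory List of [Region] objects, ROI_1 (the seed) to ROI_I.
#' @slot sizeHistory Integer voxel counts of the history regions.
#' @slot iterations Number of tracking iterations performed.
#' @slot converged `TRUE` when the final two regions have equal size.
#' @slot params The [ICETParams] used.
#' @slot tracking The [TrackingParams] used.
#' @export
#' @exportClass ICETState
setClass("ICETState",
  representation(roiHistory = "list", sizeHistory = "integer",
                 iterations = "integer", converged = "logical",
                 params = "ICETParams", tracking = "TrackingParams"))

setValidity("ICETState", function(object) {
  s <- object@sizeHistory
  if (length(object@roiHistory) != length(s))
    return("sizeHistory must parallel roiHistory")
  if (length(s) >= 2L && any(diff(s) < 0L))
    return("region sizes must be non-decreasing")
  TRUE
})

#' Along-tract profile
#'
#' Map values sampled along the voxelised path of a line of interest (LOI),
#' indexed by distance from the seed boundary in distinct-voxel steps
#' (distance 0 is the last seed voxel on the LOI).
#'
#' @slot distance Integer distances, strictly increasing from 0.
#' @slot value Map values at each distance, >= 0.
#' @slot loiVoxels The sampled voxel indices (n x 3), parallel to `distance`.
#'
#' @param distance,value,loiVoxels See slots.
#' @return A `TractProfile`.
#' @seealso [extractProfile()], [linearCompensation()], [declineStatistic()]
#' @export TractProfile
#' @exportClass TractProfile
TractProfile <- setClass("TractProfile",
  representation(distance = "numeric", value = "numeric",
                 loiVoxels = "matrix"))

setValidity("TractProfile", function(object) {
  if (length(object@distance) != length(object@value))
    return("distance and value must have equal length")
  if (length(object@distance)) {
    if (object@distance[1L] != 0) return("profile must start at distance 0")
    if (any(diff(object@distance) <= 0))
      return("distances must be strictly increasing")
    if (any(object@value < 0)) return("profile values must be >= 0")
  }
  TRUE
})
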