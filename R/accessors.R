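#' @include AllGenerics.R
NULL

#' @describeIn gridDims dimensions of a direction field
#' @export
setMethod("gridDims", "DirectionField", function(x) x@dims)

#' @describeIn gridDims dimensions of a region's grid
#' @export
setMethod("gridDims", "Region", function(x) x@dims)

#' @describeIn gridDims dimensions of a map's grid
#' @export
setMethod("gridDims", "PICoMap", function(x) dim(x@values))

#' @describeIn gridDims dimensions of a streamline set's grid
#' @export
setMethod("gridDims", "StreamlineSet", function(x) x@dims)

#' @describeIn gridDims dimensions of a phantom's grid
#' @export
setMethod("gridDims", "Phantom", function(x) x@field@dims)

#' @describeIn nEmitted emitted count of a streamline set
#' @export
setMethod("nEmitted", "StreamlineSet", function(x) x@nEmitted)

#' @describeIn nEmitted normalisation denominator of a map
#' @export
setMethod("nEmitted", "PICoMap", function(x) x@nEmitted)

#' @describeIn mapValues values of a PICo / confidence map
#' @export
setMethod("mapValues", "PICoMap", function(x) x@values)

#' @describeIn regionSize voxel count
#' @export
setMethod("regionSize", "Region", function(x) nrow(x@voxels))

#' @describeIn finalROI last region of the history
#' @export
setMethod("finalROI", "ICETState",
          function(x) x@roiHistory[[length(x@roiHistory)]])

#' @describeIn sizeHistory voxel counts over iterations
#' @export
setMethod("sizeHistory", "ICETState", function(x) x@sizeHistory)

#' @describeIn converged growth stopped before the iteration cap
#' @export
setMethod("converged", "ICETState", function(x) x@converged)

#' @describeIn trackStatus per-streamline termination status
#' @export
setMethod("trackStatus", "StreamlineSet",
          function(x) .trackStatusLevels[x@status])

#' Voxel indices of a region
#' @param region A [Region].
#' @return Integer n x 3 matrix of voxel index triplets.
#' @export
regionVoxels <- function(region) {
  stopifnot(is(region, "Region"))
  region@voxels
}

#' Number of streamlines retained in a set
#' @param x A [StreamlineSet].
#' @export
setMethod("length", "StreamlineSet", function(x) length(x@paths))

#' Extract one streamline from a set
#' @param x A [StreamlineSet].
#' @param i Streamline index.
#' @return A [Streamline-class] object.
#' @export
setMethod("[[", "StreamlineSet", function(x, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= length(x@paths))
  pts <- if (length(x@points)) x@points[[i]] else
    matrix(numeric(0), ncol = 3L)
  new("Streamline",
      points = pts,
      voxels = .coords(x@paths[[i]], x@dims),
      seedVoxel = .coords(x@seedVoxel[i], x@dims)[1L, ],
      status = .trackStatusLevels[x@status[i]])
})

#' Subset a streamline set
#' @param x A [StreamlineSet].
#' @param i Indices (integer or logical) of streamlines to keep; `nEmitted`
#'   is preserved, as for waypoint/exclusion filtering.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "StreamlineSet", function(x, i, j, ..., drop = FALSE) {
  StreamlineSet(dims = x@dims, paths = x@paths[i],
                points = if (length(x@points)) x@points[i] else list(),
                status = x@status[i], seedVoxel = x@seedVoxel[i],
                streamId = x@streamId[i], nEmitted = x@nEmitted)
})

#' @describeIn TractProfile-class coerce a profile to a data.frame with
#'   `distance` and `value` columns
#' @param x A [TractProfile].
#' @param row.names,optional,... Passed on conventionally, unused.
#' @export
as.data.frame.TractProfile <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(distance = x@distance, value = x@value)
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "TrackingParams", function(object) {
  cat(sprintf(
    "TrackingParams: inner-product threshold %.3g (max turn %.1f deg),%s maxSteps %s\n",
    object@innerProductThreshold,
    acos(object@innerProductThreshold) * 180 / pi,
    if (object@bidirectional) " bidirectional," else " forwards-only,",
    ifelse(is.na(object@maxSteps), "auto", object@maxSteps)))
})

setMethod("show", "ICETParams", function(object) {
  cat(sprintf(
    "ICETParams: %d streams/voxel, iteration threshold %.3g, global threshold %.3g\n",
    object@icetStreams, object@icetThreshold, object@globalThreshold))
})

setMethod("show", "Region", function(object) {
  cat(sprintf("Region: %d voxels on a %s grid\n", nrow(object@voxels),
              paste(object@dims, collapse = "x")))
})

setMethod("show", "DirectionField", function(object) {
  cat(sprintf(
    "DirectionField: %s grid, %d masked voxels (%d with 1 population, %d with 2)\n",
    paste(object@dims, collapse = "x"), sum(object@mask),
    sum(object@npop == 1L), sum(object@npop == 2L)))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom on a %s grid\n  bundles: %s\n  regions: %s\n",
              paste(object@field@dims, collapse = "x"),
              paste(names(object@bundleMasks), collapse = ", "),
              paste(names(object@regions), collapse = ", ")))
})

setMethod("show", "StreamlineSet", function(object) {
  cat(sprintf("StreamlineSet: %d retained of %d emitted streamlines on a %s grid\n",
              length(object@paths), object@nEmitted,
              paste(object@dims, collapse = "x")))
  if (length(object@paths)) {
    tab <- table(.trackStatusLevels[object@status])
    cat("  termination:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
  }
})

setMethod("show", "Streamline", function(object) {
  cat(sprintf("Streamline: %d points, seed voxel (%s), status %s\n",
              nrow(object@voxels), paste(object@seedVoxel, collapse = ","),
              object@status))
})

setMethod("show", "PICoMap", function(object) {
  cat(sprintf("%s: %s grid, %d emitted streamlines, %d voxels > 0, max %.4g\n",
              class(object), paste(dim(object@values), collapse = "x"),
              object@nEmitted, sum(object@values > 0), max(object@values)))
})

setMethod("show", "ICETState", function(object) {
  cat(sprintf("ICETState: %d iterations, %s, |ROI| %d -> %d\n",
              object@iterations,
              if (object@converged) "converged" else "NOT converged",
              object@sizeHistory[1L],
              object@sizeHistory[length(object@sizeHistory)]))
})

setMethod("show", "TractProfile", function(object) {
  cat(sprintf("TractProfile: %d samples, distance 0..%d\n",
              length(object@distance),
              as.integer(max(c(0, object@distance)))))
})
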