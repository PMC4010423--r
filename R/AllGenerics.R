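#' @include AllClasses.R
NULL

#' Grid dimensions of an object
#' @param x A grid-bearing object ([DirectionField], [Region], [PICoMap], ...).
#' @return Integer vector (nx, ny, nz).
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Number of emitted streamlines
#' @param x A [StreamlineSet] or [PICoMap].
#' @return Integer count of streamlines emitted before any filtering.
#' @export
setGeneric("nEmitted", function(x) standardGeneric("nEmitted"))

#' Map values as an array
#' @param x A [PICoMap] or [IntraTractConfidenceMap].
#' @return Numeric array of per-voxel values.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Number of voxels in a region
#' @param x A [Region].
#' @return Integer voxel count.
#' @export
setGeneric("regionSize", function(x) standardGeneric("regionSize"))

#' Final grown region of an ICE-T run
#' @param x An [ICETState].
#' @return The final [Region] ROI_I.
#' @export
setGeneric("finalROI", function(x) standardGeneric("finalROI"))

#' Region-size history of an ICE-T run
#' @param x An [ICETState].
#' @return Integer vector of |ROI_i| over iterations.
#' @export
setGeneric("sizeHistory", function(x) standardGeneric("sizeHistory"))

#' Convergence flag of an ICE-T run
#' @param x An [ICETState].
#' @return `TRUE` if the region stopped growing before the iteration cap.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Termination statuses of a streamline set
#' @param x A [StreamlineSet].
#' @return Character vector of per-streamline termination statuses.
#' @export
setGeneric("trackStatus", function(x) standardGeneric("trackStatus"))
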