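#' @include AllClasses.R
NULL

# unique visited linear indices per streamline
.uniquePaths <- function(streams) lapply(streams@paths, unique)

# does each streamline's path intersect the lookup table?
.hitsLUT <- function(streams, lut) {
  vapply(streams@paths, function(p) any(lut[p]), logical(1L))
}

#' Compute a PICo connection-confidence map from a streamline set
#'
#' The value at voxel v is the fraction of *emitted* streamlines whose
#' voxelised path visited v; each streamline contributes at most once per
#' voxel. Filtering (waypoints, exclusions) lowers values because the emitted
#' count, not the surviving count, is the denominator — the map reads as the
#' relative propagating success of streamlines from the seed region.
#'
#' @param streams A [StreamlineSet] (`nEmitted >= 1`).
#' @param seed Optional [Region] recorded as the map's seed reference
#'   (defaults to the set of seed voxels of `streams`).
#' @return A [PICoMap].
#' @examples
#' ph <- makeStraightBundle(10, radius = 0, dispersion = 0)
#' ss <- emitFromROI(ph@field, ph@regions$seed, 10, TrackingParams(rngSeed = 1))
#' max(mapValues(computePICo(ss)))
#' @export
computePICo <- function(streams, seed = NULL) {
  stopifnot(is(streams, "StreamlineSet"))
  if (streams@nEmitted < 1L) stop("nEmitted must be >= 1")
  counts <- .zeroArray(streams@dims)
  if (length(streams@paths)) {
    visits <- unlist(.uniquePaths(streams), use.names = FALSE)
    tab <- tabulate(visits, nbins = prod(streams@dims))
    counts[] <- tab
  }
  if (is.null(seed))
    seed <- Region(voxels = unique(streams@seedVoxel), dims = streams@dims)
  PICoMap(values = counts / streams@nEmitted,
          nEmitted = streams@nEmitted, seed = seed)
}

#' Waypoint filtering of a streamline set
#'
#' Retains exactly the streamlines whose voxelised path intersects the
#' waypoint region; all streamlines are required to pass through it. The
#' emitted count is unchanged, so downstream PICo values shrink accordingly.
#'
#' @param streams A [StreamlineSet].
#' @param waypoint A non-empty [Region].
#' @return The filtered [StreamlineSet] (possibly empty, `nEmitted`
#'   preserved).
#' @export
filterWaypoint <- function(streams, waypoint) {
  stopifnot(is(streams, "StreamlineSet"), is(waypoint, "Region"))
  .stopifnotSameGrid(streams@dims, waypoint@dims)
  if (regionSize(waypoint) == 0L) stop("waypoint region is empty")
  streams[.hitsLUT(streams, .regionLookup(waypoint))]
}

#' Exclusion-mask removal of streamlines
#'
#' Removes entirely any streamline whose voxelised path intersects the
#' exclusion region; the emitted count is unchanged.
#'
#' @param streams A [StreamlineSet].
#' @param exclusion A [Region] (may be empty, in which case this is the
#'   identity).
#' @return The filtered [StreamlineSet].
#' @export
applyExclusion <- function(streams, exclusion) {
  stopifnot(is(streams, "StreamlineSet"), is(exclusion, "Region"))
  .stopifnotSameGrid(streams@dims, exclusion@dims)
  if (regionSize(exclusion) == 0L) return(streams)
  streams[!.hitsLUT(streams, .regionLookup(exclusion))]
}

#' Threshold a confidence map into a region
#'
#' Returns the voxels whose map value is greater than or equal to `t`
#' (inclusive comparison, so `t = 1` keeps voxels visited by every emitted
#' streamline).
#'
#' @param map A [PICoMap] or [IntraTractConfidenceMap] (or a bare numeric
#'   array).
#' @param t Threshold in (0, 1].
#' @return A [Region] of supra-threshold voxels.
#' @examples
#' m <- array(0, c(2, 2, 1)); m[1, 1, 1] <- 0.5
#' regionSize(thresholdMap(m, 0.5))
#' @export
thresholdMap <- function(map, t) {
  if (length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    stop("threshold must lie in (0, 1]")
  values <- if (is(map, "PICoMap")) map@values else map
  stopifnot(length(dim(values)) == 3L)
  Region(voxels = which(values >= t), dims = dim(values))
}
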