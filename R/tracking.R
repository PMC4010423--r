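#' @include AllClasses.R
NULL

# flatten a DirectionField for the C++ core (dispersion converted to radians)
.fieldArgs <- function(field) {
  list(dims = field@dims,
       npop = as.integer(field@npop),
       dir1 = as.numeric(field@dir1),
       dir2 = as.numeric(field@dir2),
       disp1 = as.numeric(field@disp1) * pi / 180,
       disp2 = as.numeric(field@disp2) * pi / 180,
       mask = as.integer(field@mask))
}

.resolveMaxSteps <- function(params, dims) {
  if (is.na(params@maxSteps)) 10L * max(dims) else params@maxSteps
}

#' Sample one propagation direction from a voxel's fiber populations
#'
#' The elementary draw of the probabilistic tracker. With an incoming
#' direction, each population is first sign-aligned with it; populations whose
#' aligned direction has inner product >= `innerProductThreshold` with the
#' incoming direction qualify, one of them is chosen uniformly at random, and
#' its direction is perturbed by a half-normal angle (standard deviation =
#' the population's dispersion) about a uniformly random perpendicular axis.
#' If no population qualifies, or the perturbed direction violates the
#' curvature constraint, `NULL` is returned (the caller terminates the
#' streamline). Without an incoming direction (the first step), a population
#' and a sign are chosen uniformly.
#'
#' @param directions k x 3 matrix (k = 1 or 2) of unit population directions,
#'   or a single 3-vector.
#' @param dispersions Angular dispersion per population, degrees.
#' @param incoming Unit 3-vector of the previous step direction, or `NULL`.
#' @param params A [TrackingParams].
#' @param seed Substream seed for this single draw.
#' @return A unit 3-vector, or `NULL` if no direction satisfies the curvature
#'   constraint.
#' @examples
#' a <- c(1, 0, 0)
#' sampleStepDirection(a, 0, incoming = a, seed = 1)
#' @export
sampleStepDirection <- function(directions, dispersions = 0, incoming = NULL,
                                params = TrackingParams(), seed = 1) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  stopifnot(ncol(directions) == 3L, nrow(directions) >= 1L)
  dispersions <- rep_len(as.numeric(dispersions), nrow(directions))
  out <- .cppSampleStepDirection(directions, dispersions * pi / 180,
                                 if (is.null(incoming)) NULL else
                                   as.numeric(incoming),
                                 params@innerProductThreshold,
                                 as.numeric(seed))
  if (is.null(out)) NULL else as.numeric(out)
}

# shared emission core; returns a StreamlineSet (unfiltered)
.emit <- function(field, seeds, streamsPerVoxel, params, stage,
                  streamIdOffset, storePoints) {
  fa <- .fieldArgs(field)
  maxSteps <- .resolveMaxSteps(params, field@dims)
  res <- .cppEmitStreamlines(fa$dims, fa$npop, fa$dir1, fa$dir2, fa$disp1,
                             fa$disp2, fa$mask, seeds,
                             as.integer(streamsPerVoxel),
                             params@innerProductThreshold, maxSteps,
                             params@bidirectional, params@rngSeed,
                             as.integer(stage), as.integer(streamIdOffset),
                             storePoints)
  StreamlineSet(dims = field@dims, paths = res$paths,
                points = if (storePoints) res$points else list(),
                status = as.integer(res$status),
                seedVoxel = as.integer(res$seedVoxel),
                streamId = as.integer(res$streamId),
                nEmitted = length(res$paths))
}

#' Propagate a single streamline
#'
#' FACT semantics: within each visited voxel the propagation direction is
#' sampled once and held; the step advances the position to the exit face of
#' the voxel (nudged 1e-6 voxel into the next one). Propagation stops on mask
#' exit, on entering a voxel with no fiber population, on curvature failure,
#' or at `maxSteps`. With bidirectional tracking (the default) a second
#' half-track is launched with the opposite initial sign and prepended in
#' reverse, so the curvature bound also holds across the seed.
#'
#' @param field A [DirectionField].
#' @param seedVoxel Voxel index triplet inside the field mask.
#' @param params A [TrackingParams]; `rngSeed` selects the substream.
#' @param streamId Per-voxel substream id (vary to obtain different draws).
#' @return A [Streamline-class] object.
#' @examples
#' ph <- makeStraightBundle(10, radius = 0, dispersion = 0)
#' sl <- propagateStreamline(ph@field, regionVoxels(ph@regions$seed)[1, ],
#'                           TrackingParams(rngSeed = 7))
#' sl@status
#' @export
propagateStreamline <- function(field, seedVoxel, params = TrackingParams(),
                                streamId = 0L) {
  stopifnot(is(field, "DirectionField"))
  seedVoxel <- as.integer(seedVoxel)
  if (length(seedVoxel) != 3L || any(seedVoxel < 1L) ||
      any(seedVoxel > field@dims))
    stop("seed voxel out of grid bounds")
  if (!field@mask[seedVoxel[1L], seedVoxel[2L], seedVoxel[3L]])
    stop("seed voxel lies outside the field mask")
  set <- .emit(field, matrix(seedVoxel, 1L), 1L, params, stage = 1L,
               streamIdOffset = streamId, storePoints = TRUE)
  set[[1L]]
}

#' Emit streamlines from every voxel of a region
#'
#' Launches `streamsPerVoxel` streamlines from the center of every voxel in
#' `roi`. The RNG substream of each (voxel, stream) pair is derived
#' deterministically from `params@rngSeed`, so repeated calls reproduce
#' identical streamlines voxel by voxel — the property the ICE-T streamline
#' cache relies on. Waypoint and exclusion filters drop streamlines but leave
#' `nEmitted` (= voxels x streams) untouched, so PICo normalisation is always
#' over the emitted count.
#'
#' @param field A [DirectionField].
#' @param roi Seed [Region] (non-empty, inside the field mask).
#' @param streamsPerVoxel Streamlines per seed voxel, >= 1.
#' @param params A [TrackingParams].
#' @param waypoint Optional [Region]: retain only streamlines whose voxel path
#'   intersects it.
#' @param exclusions Optional list of [Region]s: remove streamlines whose
#'   voxel path intersects any of them.
#' @param storePoints Keep continuous point coordinates (set `FALSE` for large
#'   runs where only voxel paths are needed).
#' @param stage Internal RNG namespace (distinct stages draw independent
#'   substreams; the ICE-T loop and the final confidence map use different
#'   stages).
#' @param streamIdOffset First substream id (ids run `streamIdOffset` to
#'   `streamIdOffset + streamsPerVoxel - 1` in every voxel).
#' @return A [StreamlineSet].
#' @examples
#' ph <- makeStraightBundle(10, radius = 1, dispersion = 10)
#' ss <- emitFromROI(ph@field, ph@regions$seed, 5,
#'                   TrackingParams(rngSeed = 1))
#' nEmitted(ss)
#' @export
emitFromROI <- function(field, roi, streamsPerVoxel,
                        params = TrackingParams(), waypoint = NULL,
                        exclusions = list(), storePoints = TRUE,
                        stage = 1L, streamIdOffset = 0L) {
  stopifnot(is(field, "DirectionField"), is(roi, "Region"))
  .stopifnotSameGrid(roi@dims, field@dims)
  if (regionSize(roi) == 0L) stop("seed region is empty")
  if (streamsPerVoxel < 1L) stop("streamsPerVoxel must be >= 1")
  if (!all(field@mask[.lin(roi@voxels, field@dims)]))
    stop("seed region must lie inside the field mask")
  set <- .emit(field, roi@voxels, streamsPerVoxel, params, stage,
               streamIdOffset, storePoints)
  if (!is.null(waypoint)) set <- filterWaypoint(set, waypoint)
  for (ex in exclusions) set <- applyExclusion(set, ex)
  set
}
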