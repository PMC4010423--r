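#' @include tracking.R pico.R
NULL

# RNG namespaces: keep the region-growing loop and the final confidence map on
# independent substreams of the same root seed
.STAGE_TRACK <- 1L
.STAGE_ICET <- 2L
.STAGE_CONF <- 3L

# Generate `n` streamlines from each voxel (rows of `coords`), returning the
# per-voxel lists of unique visited linear-index sets.
.genStreamSets <- function(field, coords, n, tracking, stage) {
  set <- .emit(field, coords, n, tracking, stage = stage,
               streamIdOffset = 0L, storePoints = FALSE)
  sets <- lapply(set@paths, unique)
  split(sets, rep(seq_len(nrow(coords)), each = n))
}

#' Pre-generated streamline repository
#'
#' Generates (lazily, voxel by voxel) a fixed number of streamlines per voxel
#' from which smaller samples can be drawn, so that parameter sweeps over the
#' streams grid re-use one set of computations. Because every (voxel, stream)
#' substream is derived from the root seed, drawing `n` streamlines from the
#' repository is identical to generating `n` directly.
#'
#' @param field A [DirectionField].
#' @param tracking A [TrackingParams] (its `rngSeed` keys the repository).
#' @param capacity Streamlines stored per voxel (paper-style default 500).
#' @return An opaque repository object for [runICET()] / [runSweep()].
#' @export
streamlineRepository <- function(field, tracking, capacity = 500L) {
  repo <- new.env(parent = emptyenv())
  repo$field <- field
  repo$tracking <- tracking
  repo$capacity <- as.integer(capacity)
  repo$cache <- new.env(parent = emptyenv())
  class(repo) <- "StreamlineRepository"
  repo
}

# fetch >= n unique-voxel sets per voxel for the given linear indices,
# generating missing voxels in one batch
.repoGet <- function(repo, lins, n, dims) {
  if (n > repo$capacity)
    stop("repository capacity (", repo$capacity, ") below requested ", n)
  keys <- as.character(lins)
  missing <- keys[!vapply(keys, exists, logical(1L), envir = repo$cache)]
  if (length(missing)) {
    coords <- .coords(as.integer(missing), dims)
    gen <- .genStreamSets(repo$field, coords, repo$capacity, repo$tracking,
                          .STAGE_ICET)
    for (i in seq_along(missing)) assign(missing[i], gen[[i]], repo$cache)
  }
  lapply(keys, function(k) get(k, repo$cache)[seq_len(n)])
}

#' Run the ICE-T region-growing loop
#'
#' Iteratively grows the seed region along its connections. Each iteration:
#' (1) emit `icetStreams` streamlines from every voxel of the current region
#' ROI_i, with the region from two iterations earlier, ROI_(i-2), as a
#' waypoint all streamlines must pass (the original seed for the first two
#' iterations, which guarantees the seed is part of the final tract);
#' (2) threshold the resulting PICo map at `icetThreshold`; (3) set ROI_(i+1)
#' to the union of ROI_i with the supra-threshold voxels; (4) stop when the
#' region stops growing (or at `maxIterations`, flagged as non-converged).
#'
#' Streamlines are cached per voxel: only newly included voxels are tracked at
#' later iterations, and the waypoint filter is re-evaluated against the
#' current ROI_(i-2) on the cached paths. Because substreams are keyed by
#' (seed, voxel, stream id), running with the cache disabled — or against a
#' larger pre-generated repository — yields bit-identical histories.
#'
#' @param field A [DirectionField].
#' @param seed Seed [Region], non-empty and inside the field mask.
#' @param params An [ICETParams].
#' @param tracking A [TrackingParams].
#' @param waypoints Optional list of extra [Region] waypoints every counted
#'   streamline must traverse.
#' @param exclusions Optional list of [Region] exclusion masks; traversing
#'   streamlines are removed.
#' @param useCache Re-use per-voxel streamlines across iterations (identical
#'   results either way; `FALSE` only re-generates them each iteration).
#' @param repository Optional [streamlineRepository()] built on the same field
#'   and tracking parameters, shared across runs.
#' @return An [ICETState] with the full region history.
#' @examples
#' ph <- makeStraightBundle(12, radius = 1, dispersion = 20)
#' st <- runICET(ph@field, ph@regions$seed,
#'               ICETParams(icetStreams = 10, icetThreshold = 0.05),
#'               TrackingParams(rngSeed = 1))
#' converged(st); sizeHistory(st)
#' @export
runICET <- function(field, seed, params = ICETParams(),
                    tracking = TrackingParams(), waypoints = list(),
                    exclusions = list(), useCache = TRUE, repository = NULL) {
  stopifnot(is(field, "DirectionField"), is(seed, "Region"),
            is(params, "ICETParams"), is(tracking, "TrackingParams"))
  .stopifnotSameGrid(seed@dims, field@dims)
  if (regionSize(seed) == 0L) stop("seed region is empty")
  if (!all(field@mask[.lin(seed@voxels, field@dims)]))
    stop("seed region must lie inside the field mask")
  dims <- field@dims
  nvox <- prod(dims)
  streams <- params@icetStreams

  if (is.null(repository)) {
    repo <- streamlineRepository(field, tracking, capacity = streams)
  } else {
    stopifnot(inherits(repository, "StreamlineRepository"))
    repo <- repository
  }

  wlut <- lapply(waypoints, .regionLookup)
  elut <- lapply(exclusions, .regionLookup)

  seedLin <- sort(.lin(seed@voxels, dims))
  roiLin <- seedLin
  roiHistory <- list(Region(voxels = seedLin, dims = dims))
  sizeHistory <- length(seedLin)
  convergedFlag <- FALSE
  i <- 0L

  repeat {
    i <- i + 1L
    sets <- .repoGet(repo, roiLin, streams, dims)
    if (!useCache && is.null(repository))
      rm(list = ls(repo$cache), envir = repo$cache)
    allSets <- unlist(sets, recursive = FALSE, use.names = FALSE)

    wp <- if (i <= 2L) seedLin else
      .lin(roiHistory[[i - 2L]]@voxels, dims)
    wpLut <- logical(nvox)
    wpLut[wp] <- TRUE

    keep <- vapply(allSets, function(s) any(wpLut[s]), logical(1L))
    for (lut in wlut)
      keep <- keep & vapply(allSets, function(s) any(lut[s]), logical(1L))
    for (lut in elut)
      keep <- keep & !vapply(allSets, function(s) any(lut[s]), logical(1L))

    nEmit <- length(roiLin) * streams
    counts <- tabulate(unlist(allSets[keep], use.names = FALSE), nbins = nvox)
    candidate <- which(counts / nEmit >= params@icetThreshold)

    roiNext <- sort(unique(c(roiLin, candidate)))
    roiHistory[[i + 1L]] <- Region(voxels = roiNext, dims = dims)
    sizeHistory[i + 1L] <- length(roiNext)
    if (length(roiNext) == length(roiLin)) { convergedFlag <- TRUE; break }
    roiLin <- roiNext
    if (i >= params@maxIterations) break
  }

  new("ICETState", roiHistory = roiHistory,
      sizeHistory = as.integer(sizeHistory), iterations = i,
      converged = convergedFlag, params = params, tracking = tracking)
}

#' Intra-Tract Confidence map from a grown region
#'
#' Re-seeds tractography from every voxel of the final grown region ROI_I (no
#' region waypoint) and returns the normalised visitation map. Its values
#' describe how well connected each voxel is to all the other voxels within
#' the segmented tract — not the probability of connection to the original
#' seed — and, with the path-length decay removed, a single global threshold
#' can be applied directly ([segmentTract()]).
#'
#' @param field A [DirectionField].
#' @param roiFinal The grown [Region] (e.g. `finalROI(state)`), non-empty.
#' @param nStreams Streamlines emitted per region voxel.
#' @param tracking A [TrackingParams].
#' @param waypoints,exclusions Optional extra filters, as in [runICET()].
#' @return An [IntraTractConfidenceMap].
#' @export
intraTractConfidence <- function(field, roiFinal, nStreams = 100L,
                                 tracking = TrackingParams(),
                                 waypoints = list(), exclusions = list()) {
  stopifnot(is(field, "DirectionField"), is(roiFinal, "Region"))
  if (regionSize(roiFinal) == 0L) stop("region is empty")
  set <- .emit(field, roiFinal@voxels, as.integer(nStreams), tracking,
               stage = .STAGE_CONF, streamIdOffset = 0L, storePoints = FALSE)
  for (w in waypoints) set <- filterWaypoint(set, w)
  for (ex in exclusions) set <- applyExclusion(set, ex)
  pm <- computePICo(set, seed = roiFinal)
  IntraTractConfidenceMap(values = pm@values, nEmitted = pm@nEmitted,
                          seed = roiFinal)
}

#' Segment a confidence map with a global threshold
#'
#' Identical contract to [thresholdMap()], re-exported under the name used for
#' the final segmentation step: on an Intra-Tract Confidence map, lowering the
#' global threshold broadens the cross-sectional area of the segmented tract
#' rather than shifting its end point.
#'
#' @param map An [IntraTractConfidenceMap] (or any map accepted by
#'   [thresholdMap()]).
#' @param globalThreshold Threshold in (0, 1].
#' @return A [Region].
#' @export
segmentTract <- function(map, globalThreshold) {
  thresholdMap(map, globalThreshold)
}
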