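#' @include icet.R phantom.R
NULL

#' Load a run configuration from JSON
#'
#' A single JSON file describes an experiment: the phantom (either a `phantom`
#' object with a `kind` of `"straight"`, `"crossing"` or `"branching"` plus
#' geometry fields, or a `phantomDir` pointing to an [exportPhantom()]
#' directory), optional `tracking` and `icet` parameter objects, an optional
#' `sweep` object with `icetThreshold` and/or `icetStreams` grids, the root
#' `rngSeed`, and an `outputDir`. Referenced paths must exist at load time;
#' sweep grids must be non-empty when present.
#'
#' @param path Path to the JSON configuration.
#' @return A list with elements `phantom` ([Phantom]), `tracking`
#'   ([TrackingParams]), `icet` ([ICETParams]), `sweep` (list of grids or
#'   `NULL`), `rngSeed` and `outputDir`.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom <- if (!is.null(cfg$phantomDir)) {
    if (!dir.exists(cfg$phantomDir))
      stop("phantomDir does not exist: ", cfg$phantomDir)
    importPhantom(cfg$phantomDir)
  } else if (!is.null(cfg$phantom)) {
    p <- cfg$phantom
    kind <- p$kind
    p$kind <- NULL
    maker <- switch(kind,
                    straight = makeStraightBundle,
                    crossing = makeCrossingPhantom,
                    branching = makeBranchingPhantom,
                    stop("unknown phantom kind: ", kind))
    do.call(maker, p)
  } else stop("config must provide 'phantom' or 'phantomDir'")
  rngSeed <- if (is.null(cfg$rngSeed)) 1 else cfg$rngSeed
  trackingArgs <- if (is.null(cfg$tracking)) list() else as.list(cfg$tracking)
  if (is.null(trackingArgs$rngSeed)) trackingArgs$rngSeed <- rngSeed
  tracking <- do.call(TrackingParams, trackingArgs)
  icet <- do.call(ICETParams,
                  if (is.null(cfg$icet)) list() else as.list(cfg$icet))
  sweep <- cfg$sweep
  if (!is.null(sweep)) {
    sweep <- lapply(as.list(sweep), as.numeric)
    if (any(!lengths(sweep)))
      stop("sweep grids must be non-empty")
  }
  list(phantom = phantom, tracking = tracking, icet = icet, sweep = sweep,
       rngSeed = rngSeed, outputDir = cfg$outputDir)
}

#' Parameter sweep over the ICE-T grid
#'
#' Runs ICE-T once per (streams, threshold) grid point and tabulates the final
#' region size, the iterations to convergence and the convergence flag. All
#' grid points draw their streamlines from one shared per-voxel repository
#' (generated lazily at the largest streams value), so a sweep re-uses every
#' computed streamline — and, because substreams are keyed by (seed, voxel,
#' stream id), its results are identical to independent runs. Per-cell
#' failures are recorded in the `error` column and the sweep continues.
#'
#' @param field A [DirectionField].
#' @param seed Seed [Region].
#' @param icetThresholds Numeric grid of per-iteration thresholds.
#' @param icetStreams Integer grid of streams-per-voxel values.
#' @param tracking A [TrackingParams].
#' @param globalThreshold,maxIterations Passed into each run's [ICETParams].
#' @param repository Optional shared [streamlineRepository()] (defaults to a
#'   fresh one with capacity `max(icetStreams)`).
#' @return A data.frame with one row per grid point: `icetStreams`,
#'   `icetThreshold`, `roiSize`, `iterations`, `converged`, `error`.
#' @export
runSweep <- function(field, seed, icetThresholds, icetStreams,
                     tracking = TrackingParams(), globalThreshold = 0.005,
                     maxIterations = 200L, repository = NULL) {
  stopifnot(length(icetThresholds) >= 1L, length(icetStreams) >= 1L)
  if (is.null(repository))
    repository <- streamlineRepository(field, tracking,
                                       capacity = max(icetStreams))
  grid <- expand.grid(icetStreams = as.integer(icetStreams),
                      icetThreshold = as.numeric(icetThresholds))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    params <- ICETParams(icetStreams = grid$icetStreams[i],
                         icetThreshold = grid$icetThreshold[i],
                         globalThreshold = globalThreshold,
                         maxIterations = maxIterations)
    tryCatch({
      st <- runICET(field, seed, params, tracking, repository = repository)
      data.frame(roiSize = regionSize(finalROI(st)),
                 iterations = st@iterations, converged = st@converged,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(roiSize = NA_integer_, iterations = NA_integer_,
                 converged = NA, error = conditionMessage(e))
    })
  })
  cbind(grid, do.call(rbind, res))
}

#' Write a reproducibility log for a run
#'
#' Records every parameter, seed and package version as JSON so that an
#' experiment can be regenerated from its log alone.
#'
#' @param path Output JSON path.
#' @param ... Named entries (parameter objects are flattened to their slots).
#' @return `path`, invisibly.
#' @export
writeRunLog <- function(path, ...) {
  entries <- list(...)
  flatten <- function(x) {
    if (!isS4(x)) return(x)
    sl <- methods::slotNames(class(x))
    stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
  }
  out <- lapply(entries, flatten)
  out$package <- "icetrack"
  out$version <- as.character(utils::packageVersion("icetrack"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
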