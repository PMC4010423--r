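#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# tube geometry
# ---------------------------------------------------------------------------
# A bundle is the set of voxels whose center lies within distance r of the
# centerline segment from p0 (a voxel center) along unit axis a to
# p0 + (L - 1) a: point-to-segment distance, i.e. a cylinder with rounded
# caps. All geometry is deterministic: the dispersion parameter is stored in
# the field, never sampled here.

.tubeBBox <- function(p0, axis, len, radius) {
  p1 <- p0 + axis * (len - 1)
  list(lo = pmin(p0, p1) - radius - 0.5, hi = pmax(p0, p1) + radius + 0.5)
}

.rasterTube <- function(p0, axis, len, radius, dims) {
  bb <- .tubeBBox(p0, axis, len, radius)
  lo <- pmax(1L, floor(bb$lo))
  hi <- pmin(dims, ceiling(bb$hi))
  m <- array(FALSE, dims)
  if (any(lo > hi)) return(m)
  xs <- lo[1L]:hi[1L]; ys <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  w <- sweep(g, 2L, p0)
  t <- pmin(pmax(as.vector(w %*% axis), 0), len - 1)
  d2 <- rowSums((w - outer(t, axis))^2)
  inside <- d2 <= (radius + 1e-9)^2
  m[.lin(g[inside, , drop = FALSE], dims)] <- TRUE
  m
}

.tubeCenterline <- function(p0, axis, len, dims) {
  ts <- seq(0, len - 1, by = 0.25)
  pts <- sweep(outer(ts, axis), 2L, p0, `+`)
  vox <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
  cl <- vox[keep, , drop = FALSE]
  storage.mode(cl) <- "integer"
  colnames(cl) <- c("x", "y", "z")
  cl
}

# cross-section of a tube: voxels of `mask` whose axial projection falls in
# [t0 - 0.5, t0 + 0.5)
.tubeSlice <- function(mask, p0, axis, t0) {
  v <- .maskVoxels(mask)
  t <- as.vector(sweep(v, 2L, p0) %*% axis)
  keep <- t >= t0 - 0.5 & t < t0 + 0.5
  Region(voxels = v[keep, , drop = FALSE], dims = dim(mask))
}

# Place a set of tubes (abstract coordinates) on a grid: either size the grid
# to fit all tubes plus a 2-voxel margin, or center them in a caller-supplied
# grid and fail if the margin cannot be honored.
.placeTubes <- function(tubes, gridShape, margin = 2) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (tb in tubes) {
    bb <- .tubeBBox(tb$p0, tb$axis, tb$len, tb$radius)
    lo <- pmin(lo, bb$lo); hi <- pmax(hi, bb$hi)
  }
  if (is.null(gridShape)) {
    shift <- margin + 1 - floor(lo)
    dims <- .checkDims(ceiling(hi + shift) + margin)
  } else {
    dims <- .checkDims(gridShape)
    shift <- round((dims + 1 - (hi + lo)) / 2)
    if (any(lo + shift < margin + 0.5) || any(hi + shift > dims - margin + 0.5))
      stop("bundle (plus a ", margin, "-voxel margin) exceeds the grid")
  }
  list(dims = dims,
       tubes = lapply(tubes, function(tb) { tb$p0 <- tb$p0 + shift; tb }))
}

.unitAxis <- function(axis) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (length(axis) != 3L || n == 0) stop("axis must be a non-zero 3-vector")
  axis / n
}

# Assemble a DirectionField from per-bundle masks and directions. Voxels
# belonging to >= 2 bundles carry the two directions given by `crossDirs`
# (a function of the membership pattern); others carry their bundle's
# direction. Background voxels stay masked-in with zero populations.
.fieldFromBundles <- function(dims, masks, dirs, dispersion) {
  npop <- array(0L, dims)
  dir1 <- array(0, c(dims, 3L)); dir2 <- array(0, c(dims, 3L))
  disp1 <- .zeroArray(dims); disp2 <- .zeroArray(dims)
  n <- prod(dims)
  memb <- vapply(masks, as.vector, logical(n))
  cnt <- rowSums(memb)
  d1 <- matrix(0, n, 3L); d2 <- matrix(0, n, 3L)
  single <- which(cnt == 1L)
  for (b in seq_along(masks)) {
    w <- single[memb[single, b]]
    if (length(w))
      d1[w, ] <- matrix(dirs[[b]], length(w), 3L, byrow = TRUE)
  }
  multi <- which(cnt >= 2L)
  for (v in multi) {
    # with >2 overlapping bundles keep the two last-listed (the children of a
    # branch, when the trunk is listed first)
    bs <- utils::tail(which(memb[v, ]), 2L)
    d1[v, ] <- dirs[[bs[1L]]]
    d2[v, ] <- dirs[[bs[2L]]]
  }
  npop[single] <- 1L
  npop[multi] <- 2L
  dir1 <- array(d1, c(dims, 3L))
  dir2 <- array(d2, c(dims, 3L))
  disp1[cnt >= 1L] <- dispersion
  disp2[cnt >= 2L] <- dispersion
  DirectionField(dims = dims, npop = npop, dir1 = dir1, dir2 = dir2,
                 disp1 = disp1, disp2 = disp2, mask = array(TRUE, dims))
}

# ---------------------------------------------------------------------------
# phantom constructors
# ---------------------------------------------------------------------------

#' Straight-bundle phantom
#'
#' A single straight fiber bundle: the test bed on which the path-length
#' dependency of probabilistic tractography appears as a monotonic decay of
#' connection confidence with distance from an end seed. The phantom carries
#' the bundle mask, its centerline, a seed region (the bundle cross-section at
#' the start end) and a `distal` region (the far-end cross-section).
#'
#' @param length Bundle length in voxels (centerline spans `length` voxels),
#'   >= 3.
#' @param radius Tube radius in voxels, >= 0 (0 gives a single line of voxels
#'   for an axis-aligned bundle).
#' @param axis Bundle direction (3-vector, normalised internally).
#' @param dispersion Angular dispersion of the fiber population, degrees.
#' @param gridShape Grid dimensions; `NULL` (default) sizes the grid to the
#'   bundle plus a 2-voxel margin. A supplied grid that cannot hold the bundle
#'   plus margin is an error.
#' @return A [Phantom].
#' @examples
#' ph <- makeStraightBundle(length = 10, radius = 1, dispersion = 0)
#' sum(ph@bundleMasks$bundle)
#' @export
makeStraightBundle <- function(length, radius, axis = c(1, 0, 0),
                               dispersion = 0, gridShape = NULL) {
  if (length < 3) stop("bundle length must be >= 3 voxels")
  if (radius < 0) stop("radius must be >= 0")
  if (dispersion < 0 || dispersion >= 90)
    stop("dispersion must lie in [0, 90) degrees")
  axis <- .unitAxis(axis)
  pl <- .placeTubes(list(list(p0 = c(0, 0, 0), axis = axis, len = length,
                              radius = radius)), gridShape)
  tb <- pl$tubes[[1L]]
  mask <- .rasterTube(tb$p0, axis, length, radius, pl$dims)
  field <- .fieldFromBundles(pl$dims, list(bundle = mask), list(axis),
                             dispersion)
  Phantom(field = field,
          bundleMasks = list(bundle = mask),
          centerlines = list(bundle = .tubeCenterline(tb$p0, axis, length,
                                                      pl$dims)),
          regions = list(seed = .tubeSlice(mask, tb$p0, axis, 0),
                         distal = .tubeSlice(mask, tb$p0, axis, length - 1)))
}

#' Two-bundle crossing phantom
#'
#' Two straight bundles intersecting at a stated angle, emulating a complex
#' crossing-fiber region (a centrum-semiovale analogue): voxels inside both
#' tubes carry both fiber populations, so a streamline traversing the crossing
#' must repeatedly choose between them, which makes the confidence drop across
#' the crossing super-exponential. Bundle 1 runs along x; bundle 2 lies in the
#' x-y plane at `angle` degrees to it; both are centered on the crossing.
#' The seed region is bundle 1's start cross-section; `distal` its far end.
#'
#' @param angle Crossing angle in degrees, in [10, 90].
#' @param bundleLength Length of each bundle, voxels.
#' @param radius Tube radius, voxels (>= 1 recommended so the oblique bundle
#'   rasterises contiguously).
#' @param dispersion Angular dispersion, degrees.
#' @param gridShape Grid dimensions, or `NULL` to fit automatically.
#' @return A [Phantom] with bundles `bundle1`, `bundle2` and a `crossing`
#'   region (voxels inside both tubes).
#' @examples
#' ph <- makeCrossingPhantom(angle = 90, bundleLength = 15, radius = 1)
#' regionSize(ph@regions$crossing) > 0
#' @export
makeCrossingPhantom <- function(angle, bundleLength = 40, radius = 2,
                                dispersion = 0, gridShape = NULL) {
  if (angle < 10 || angle > 90)
    stop("crossing angle must lie in [10, 90] degrees")
  if (bundleLength < 3) stop("bundle length must be >= 3 voxels")
  th <- angle * pi / 180
  a1 <- c(1, 0, 0)
  a2 <- c(cos(th), sin(th), 0)
  # integer mid-point so bundle 1 (and hence the seed slice) sits on voxel
  # centers; bundle 2 crosses it there
  half <- floor((bundleLength - 1) / 2)
  tubes <- list(list(p0 = -a1 * half, axis = a1, len = bundleLength,
                     radius = radius),
                list(p0 = -a2 * half, axis = a2, len = bundleLength,
                     radius = radius))
  pl <- .placeTubes(tubes, gridShape)
  m1 <- .rasterTube(pl$tubes[[1L]]$p0, a1, bundleLength, radius, pl$dims)
  m2 <- .rasterTube(pl$tubes[[2L]]$p0, a2, bundleLength, radius, pl$dims)
  field <- .fieldFromBundles(pl$dims, list(bundle1 = m1, bundle2 = m2),
                             list(a1, a2), dispersion)
  Phantom(field = field,
          bundleMasks = list(bundle1 = m1, bundle2 = m2),
          centerlines = list(
            bundle1 = .tubeCenterline(pl$tubes[[1L]]$p0, a1, bundleLength,
                                      pl$dims),
            bundle2 = .tubeCenterline(pl$tubes[[2L]]$p0, a2, bundleLength,
                                      pl$dims)),
          regions = list(
            seed = .tubeSlice(m1, pl$tubes[[1L]]$p0, a1, 0),
            distal = .tubeSlice(m1, pl$tubes[[1L]]$p0, a1, bundleLength - 1),
            crossing = regionFromMask(m1 & m2)))
}

#' Branching-bundle phantom
#'
#' A trunk bundle that splits into two child bundles: the test bed for
#' false-positive propagation along branches. Branch-point voxels (inside both
#' child tubes) carry both child directions, so a streamline arriving along the
#' trunk picks a child uniformly at random wherever both satisfy the curvature
#' constraint. With `branchAngle = 0` the children coincide and the phantom
#' degenerates to a straight bundle.
#'
#' @param branchDistance Trunk length in voxels before the split, >= 3.
#' @param branchAngle Total angle between the two children, degrees
#'   (each child deviates by half of it from the trunk axis).
#' @param radius Tube radius, voxels.
#' @param dispersion Angular dispersion, degrees.
#' @param gridShape Grid dimensions, or `NULL` to fit automatically.
#' @param childLength Length of each child bundle beyond the branch point
#'   (default: `branchDistance`).
#' @return A [Phantom] with bundles `trunk`, `child1`, `child2`, regions
#'   `seed`, `distal1`, `distal2` and `branch` (voxels inside both children).
#' @examples
#' ph <- makeBranchingPhantom(branchDistance = 8, branchAngle = 45, radius = 1)
#' names(ph@bundleMasks)
#' @export
makeBranchingPhantom <- function(branchDistance, branchAngle, radius = 2,
                                 dispersion = 0, gridShape = NULL,
                                 childLength = branchDistance) {
  if (branchDistance < 3) stop("branchDistance must be >= 3 voxels")
  if (branchAngle < 0 || branchAngle > 120)
    stop("branchAngle must lie in [0, 120] degrees")
  phi <- branchAngle / 2 * pi / 180
  ax <- c(1, 0, 0)
  c1 <- c(cos(phi), sin(phi), 0)
  c2 <- c(cos(phi), -sin(phi), 0)
  b <- c(branchDistance - 1, 0, 0)  # branch point (trunk end)
  tubes <- list(list(p0 = c(0, 0, 0), axis = ax, len = branchDistance,
                     radius = radius),
                list(p0 = b, axis = c1, len = childLength + 1, radius = radius),
                list(p0 = b, axis = c2, len = childLength + 1, radius = radius))
  pl <- .placeTubes(tubes, gridShape)
  mt <- .rasterTube(pl$tubes[[1L]]$p0, ax, branchDistance, radius, pl$dims)
  m1 <- .rasterTube(pl$tubes[[2L]]$p0, c1, childLength + 1, radius, pl$dims)
  m2 <- .rasterTube(pl$tubes[[3L]]$p0, c2, childLength + 1, radius, pl$dims)
  field <- .fieldFromBundles(pl$dims,
                             list(trunk = mt, child1 = m1, child2 = m2),
                             list(ax, c1, c2), dispersion)
  Phantom(field = field,
          bundleMasks = list(trunk = mt, child1 = m1, child2 = m2),
          centerlines = list(
            trunk = .tubeCenterline(pl$tubes[[1L]]$p0, ax, branchDistance,
                                    pl$dims),
            child1 = .tubeCenterline(pl$tubes[[2L]]$p0, c1, childLength + 1,
                                     pl$dims),
            child2 = .tubeCenterline(pl$tubes[[3L]]$p0, c2, childLength + 1,
                                     pl$dims)),
          regions = list(
            seed = .tubeSlice(mt, pl$tubes[[1L]]$p0, ax, 0),
            distal1 = .tubeSlice(m1, pl$tubes[[2L]]$p0, c1, childLength),
            distal2 = .tubeSlice(m2, pl$tubes[[3L]]$p0, c2, childLength),
            branch = regionFromMask(m1 & m2)))
}

# ---------------------------------------------------------------------------
# phantom export / import
# ---------------------------------------------------------------------------

#' Export / import a phantom as NIfTI volumes plus JSON centerlines
#'
#' `exportPhantom()` writes the direction field (one 4-D volume per fiber
#' population plus dispersion, population-count and mask volumes), every bundle
#' mask and region as NIfTI, and the centerlines as a JSON file.
#' `importPhantom()` reads the directory back into an equivalent [Phantom].
#'
#' @param phantom A [Phantom].
#' @param dir Output (input) directory.
#' @return `exportPhantom()` returns `dir` invisibly; `importPhantom()` a
#'   [Phantom].
#' @export
exportPhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "Phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- phantom@field
  writeVolume(f@dir1, file.path(dir, "dir1.nii.gz"))
  writeVolume(f@dir2, file.path(dir, "dir2.nii.gz"))
  writeVolume(f@disp1, file.path(dir, "disp1.nii.gz"))
  writeVolume(f@disp2, file.path(dir, "disp2.nii.gz"))
  writeVolume(f@npop, file.path(dir, "npop.nii.gz"))
  writeVolume(f@mask * 1L, file.path(dir, "mask.nii.gz"))
  for (nm in names(phantom@bundleMasks))
    writeVolume(phantom@bundleMasks[[nm]] * 1L,
                file.path(dir, sprintf("bundle_%s.nii.gz", nm)))
  for (nm in names(phantom@regions))
    writeVolume(regionToMask(phantom@regions[[nm]]) * 1L,
                file.path(dir, sprintf("region_%s.nii.gz", nm)))
  jsonlite::write_json(
    lapply(phantom@centerlines, function(m) unname(apply(m, 1L, identity,
                                                         simplify = FALSE))),
    file.path(dir, "centerlines.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname exportPhantom
#' @export
importPhantom <- function(dir) {
  rd <- function(nm) readVolume(file.path(dir, nm))
  npop <- rd("npop.nii.gz"); storage.mode(npop) <- "integer"
  dims <- dim(npop)
  field <- DirectionField(dims = dims, npop = array(npop, dims),
                          dir1 = rd("dir1.nii.gz"), dir2 = rd("dir2.nii.gz"),
                          disp1 = array(rd("disp1.nii.gz"), dims),
                          disp2 = array(rd("disp2.nii.gz"), dims),
                          mask = rd("mask.nii.gz") != 0)
  bfiles <- list.files(dir, "^bundle_.*\\.nii\\.gz$")
  bundles <- lapply(bfiles, function(f) rd(f) != 0)
  names(bundles) <- sub("^bundle_(.*)\\.nii\\.gz$", "\\1", bfiles)
  rfiles <- list.files(dir, "^region_.*\\.nii\\.gz$")
  regions <- lapply(rfiles, function(f) regionFromMask(rd(f) != 0))
  names(regions) <- sub("^region_(.*)\\.nii\\.gz$", "\\1", rfiles)
  cls <- jsonlite::read_json(file.path(dir, "centerlines.json"))
  centerlines <- lapply(cls, function(l) {
    m <- do.call(rbind, lapply(l, function(p) as.integer(unlist(p))))
    colnames(m) <- c("x", "y", "z")
    m
  })
  Phantom(field = field, bundleMasks = bundles, centerlines = centerlines,
          regions = regions)
}
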