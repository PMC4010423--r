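# Shared fixtures, built in code.

# brute-force tube rasterization oracle: every grid voxel whose
# point-to-segment distance to the centerline is <= radius
oracleTubeMask <- function(p0, axis, len, radius, dims) {
  axis <- axis / sqrt(sum(axis^2))
  m <- array(FALSE, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    w <- c(x, y, z) - p0
    t <- min(max(sum(w * axis), 0), len - 1)
    if (sum((w - t * axis)^2) <= radius^2 + 1e-9) m[x, y, z] <- TRUE
  }
  m
}

# deterministic FACT voxel-walk oracle for a zero-dispersion field: from the
# center of `seed`, always step along the (sign-aligned) voxel direction to
# the exit face; returns the ordered voxel path (including the final voxel
# entered before termination)
oracleWalk <- function(field, seed, sign = 1) {
  dims <- gridDims(field)
  pos <- as.numeric(seed)
  vox <- as.integer(seed)
  path <- matrix(vox, 1L)
  incoming <- NULL
  repeat {
    np <- field@npop[vox[1], vox[2], vox[3]]
    if (np == 0L) return(path)
    d <- field@dir1[vox[1], vox[2], vox[3], ]
    if (is.null(incoming)) d <- sign * d
    else if (sum(d * incoming) < 0) d <- -d
    if (!is.null(incoming) && sum(d * incoming) < 0.5) return(path)
    tt <- Inf
    for (a in 1:3) {
      if (d[a] > 1e-12) tt <- min(tt, (vox[a] + 0.5 - pos[a]) / d[a])
      else if (d[a] < -1e-12) tt <- min(tt, (vox[a] - 0.5 - pos[a]) / d[a])
    }
    pos <- pos + (tt + 1e-6) * d
    nv <- as.integer(round(pos))
    if (any(nv < 1L) || any(nv > dims)) return(path)
    vox <- nv
    path <- rbind(path, vox)
    incoming <- d
    if (nrow(path) > 10L * max(dims)) return(path)
  }
}

# single-population straight field along +x of given length at row (y0, z0),
# on an otherwise empty (masked-in) grid
straightLineField <- function(len, dims, y0 = 2L, z0 = 2L, x0 = 2L,
                              dispersion = 0) {
  npop <- array(0L, dims)
  dir1 <- array(0, c(dims, 3L))
  disp1 <- array(0, dims)
  xs <- x0:(x0 + len - 1L)
  npop[xs, y0, z0] <- 1L
  dir1[xs, y0, z0, 1] <- 1
  disp1[xs, y0, z0] <- dispersion
  DirectionField(dims = dims, npop = npop, dir1 = dir1, disp1 = disp1)
}

# hand-built StreamlineSet from a list of voxel-coordinate matrices
handSet <- function(voxelPaths, dims, nEmitted = length(voxelPaths)) {
  paths <- lapply(voxelPaths, function(v) {
    v <- matrix(as.integer(v), ncol = 3L)
    as.integer(v[, 1L] + dims[1L] * ((v[, 2L] - 1L) + dims[2L] * (v[, 3L] - 1L)))
  })
  pts <- lapply(voxelPaths, function(v) matrix(as.numeric(v), ncol = 3L))
  StreamlineSet(dims = as.integer(dims), paths = paths, points = pts,
                status = rep(2L, length(paths)),
                seedVoxel = vapply(paths, `[`, integer(1L), 1L),
                streamId = seq_along(paths) - 1L,
                nEmitted = as.integer(nEmitted))
}

# study-condition phantoms used by the acceptance experiments
studyStraight <- function(dispersion = 20)
  makeStraightBundle(length = 40, radius = 2, dispersion = dispersion)

studyCrossing <- function(dispersion = 20)
  makeCrossingPhantom(angle = 60, bundleLength = 40, radius = 2,
                      dispersion = dispersion)

# proximal/distal split of a profile around the crossing of `phantom`
# (bundle1 centerline), excluding a 2-voxel margin around the crossing and
# the first 5 near-seed samples
crossingSplit <- function(phantom, profile) {
  cl <- phantom@centerlines$bundle1
  oncross <- regionToMask(phantom@regions$crossing)[cl]
  lo <- min(which(oncross)) - 1L
  hi <- max(which(oncross)) - 1L
  d <- profile@distance
  list(prox = profile@value[d >= 5 & d < lo - 2],
       dist = profile@value[d > hi + 2])
}
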