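dims <- c(10L, 5L, 5L)

test_that("PICo values are visitation fractions over the emitted count", {
  # hand-built set: 3 streamlines, one shared voxel
  A <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  B <- rbind(c(2, 2, 2), c(3, 3, 2))
  C <- rbind(c(5, 5, 5))
  ss <- handSet(list(A, B, C), dims)
  pm <- computePICo(ss)
  v <- mapValues(pm)
  expect_equal(v[2, 2, 2], 2 / 3)
  expect_equal(v[3, 2, 2], 1 / 3)
  expect_equal(v[5, 5, 5], 1 / 3)
  expect_equal(v[1, 1, 1], 0)
  expect_equal(max(v), 2 / 3)
  # revisits count once: a looping path contributes 1 per voxel
  loop <- rbind(c(2, 2, 2), c(3, 2, 2), c(2, 2, 2))
  expect_equal(mapValues(computePICo(handSet(list(loop), dims)))[2, 2, 2], 1)
  # normalization identity: values * nEmitted sum to the visitation count
  expect_equal(sum(mapValues(pm)) * nEmitted(pm), 3 + 2 + 1)
})

test_that("single-voxel seed keeps value 1 at the seed under dispersion", {
  ph <- makeStraightBundle(10, radius = 1, dispersion = 25)
  sv <- regionVoxels(ph@regions$seed)[1, , drop = FALSE]
  r <- Region(sv, dims = gridDims(ph))
  ss <- emitFromROI(ph@field, r, 200, TrackingParams(rngSeed = 3),
                    storePoints = FALSE)
  v <- mapValues(computePICo(ss))
  expect_equal(v[sv[1], sv[2], sv[3]], 1)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("deterministic-field PICo equals the walked-path indicator", {
  f <- straightLineField(len = 12, dims = c(16L, 4L, 4L))
  r <- Region(matrix(c(2L, 2L, 2L), 1L), dims = gridDims(f))
  ss <- emitFromROI(f, r, 50, TrackingParams(rngSeed = 8), storePoints = FALSE)
  pm <- computePICo(ss)
  # with zero dispersion every bidirectional streamline walks the same path
  oracleF <- oracleWalk(f, c(2L, 2L, 2L), sign = 1)
  oracleB <- oracleWalk(f, c(2L, 2L, 2L), sign = -1)
  expected <- array(0, gridDims(f))
  expected[rbind(oracleF, oracleB)] <- 1
  expect_identical(mapValues(pm), expected)
})

test_that("waypoint and exclusion filters follow set semantics", {
  A <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  B <- rbind(c(2, 2, 2), c(3, 3, 2))
  C <- rbind(c(5, 5, 5), c(6, 5, 5))
  ss <- handSet(list(A, B, C), dims)
  wp <- Region(rbind(c(3, 2, 2), c(3, 3, 2)), dims = dims)
  kept <- filterWaypoint(ss, wp)
  expect_identical(length(kept), 2L)
  expect_identical(nEmitted(kept), 3L)
  expect_identical(kept@paths, ss@paths[1:2])

  # whole grid as waypoint: identity
  all <- Region(which(array(TRUE, dims)), dims = dims)
  expect_identical(filterWaypoint(ss, all)@paths, ss@paths)
  # disjoint waypoint: empty result, emitted count preserved
  far <- Region(rbind(c(10, 1, 1)), dims = dims)
  expect_identical(length(filterWaypoint(ss, far)), 0L)
  expect_identical(nEmitted(filterWaypoint(ss, far)), 3L)

  # exclusion is the complement predicate
  excl <- applyExclusion(ss, wp)
  expect_identical(excl@paths, ss@paths[3])
  expect_identical(applyExclusion(ss, far)@paths, ss@paths)
  expect_identical(length(applyExclusion(ss, all)), 0L)

  # filters commute
  a <- applyExclusion(filterWaypoint(ss, wp), far)
  b <- filterWaypoint(applyExclusion(ss, far), wp)
  expect_identical(a@paths, b@paths)
  expect_identical(nEmitted(a), nEmitted(b))
})

test_that("thresholding is inclusive and monotone", {
  m <- array(0, dims)
  m[1, 1, 1] <- 0.004
  m[2, 1, 1] <- 0.005
  m[3, 1, 1] <- 0.2
  r <- thresholdMap(m, 0.005)
  expect_identical(regionSize(r), 2L)
  expect_setequal(regionVoxels(r)[, 1], c(2L, 3L))

  m[4, 1, 1] <- 1
  expect_identical(regionVoxels(thresholdMap(m, 1)),
                   matrix(c(4L, 1L, 1L), 1L, dimnames = list(NULL, c("x", "y", "z"))))
  expect_identical(regionSize(thresholdMap(m, 0.004)), 4L)

  # nesting over a threshold ladder
  ph <- makeStraightBundle(12, radius = 1, dispersion = 20)
  ss <- emitFromROI(ph@field, ph@regions$seed, 50, TrackingParams(rngSeed = 2),
                    storePoints = FALSE)
  pm <- computePICo(ss)
  ts <- c(0.01, 0.05, 0.1, 0.5)
  regs <- lapply(ts, function(t) regionToMask(thresholdMap(pm, t)))
  for (i in seq_len(length(ts) - 1L))
    expect_true(all(regs[[i]] | !regs[[i + 1L]]))

  expect_error(thresholdMap(m, 0), "threshold")
  expect_error(thresholdMap(m, 1.5), "threshold")
})

test_that("branch-point population choice splits streamlines 50/50", {
  # exact two-outcome field: one branch voxel carries both child directions,
  # each child path is laid along the corresponding deterministic walk, so
  # every streamline ends on exactly one of the two enumerated outcomes
  dims2 <- c(24L, 19L, 5L)
  # children leave the branch voxel through opposite y faces on their first
  # step, so the two enumerated outcome paths never share a voxel
  c1 <- c(0.6, 0.8, 0)
  c2 <- c(0.6, -0.8, 0)
  npop <- array(0L, dims2)
  dir1 <- array(0, c(dims2, 3L))
  dir2 <- array(0, c(dims2, 3L))
  trunk <- cbind(2:8, 10L, 3L)
  npop[trunk] <- 1L
  for (a in 1:3) dir1[cbind(trunk, a)] <- c(1, 0, 0)[a]
  b <- c(9L, 10L, 3L)
  npop[b[1], b[2], b[3]] <- 2L
  dir1[b[1], b[2], b[3], ] <- c1
  dir2[b[1], b[2], b[3], ] <- c2
  f <- DirectionField(dims = dims2, npop = npop, dir1 = dir1, dir2 = dir2)
  # lay each child along the walk the tracker itself would take
  for (cd in list(c1, c2)) {
    pos <- as.numeric(b); vox <- b
    for (step in 1:12) {
      tt <- min(ifelse(cd > 1e-12, (vox + 0.5 - pos) / cd,
                       ifelse(cd < -1e-12, (vox - 0.5 - pos) / cd, Inf)))
      pos <- pos + (tt + 1e-6) * cd
      vox <- as.integer(round(pos))
      if (any(vox < 1L) || any(vox > dims2)) break
      if (f@npop[vox[1], vox[2], vox[3]] == 0L) {
        f@npop[vox[1], vox[2], vox[3]] <- 1L
        f@dir1[vox[1], vox[2], vox[3], ] <- cd
      }
    }
  }
  ends <- list(which(f@npop > 0 & slice.index(f@npop, 2) > 10L),
               which(f@npop > 0 & slice.index(f@npop, 2) < 10L))
  r <- Region(matrix(c(2L, 10L, 3L), 1L), dims = dims2)
  ss <- emitFromROI(f, r, 10000, TrackingParams(rngSeed = 13),
                    storePoints = FALSE)
  h1 <- vapply(ss@paths, function(p) any(p %in% ends[[1]]), logical(1L))
  h2 <- vapply(ss@paths, function(p) any(p %in% ends[[2]]), logical(1L))
  expect_true(all(xor(h1, h2)))  # every streamline takes exactly one branch
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(h1) - 0.5), 3 * se)
})

test_that("rasterized branching phantom splits symmetrically", {
  ph <- makeBranchingPhantom(branchDistance = 10, branchAngle = 45, radius = 1,
                             dispersion = 0, childLength = 15)
  ss <- emitFromROI(ph@field, ph@regions$seed,
                    ceiling(1e4 / regionSize(ph@regions$seed)),
                    TrackingParams(rngSeed = 2), storePoints = FALSE)
  l1 <- which(regionToMask(ph@regions$distal1))
  l2 <- which(regionToMask(ph@regions$distal2))
  h1 <- vapply(ss@paths, function(p) any(p %in% l1), logical(1L))
  h2 <- vapply(ss@paths, function(p) any(p %in% l2), logical(1L))
  n <- sum(h1) + sum(h2)
  expect_gt(n, 1000)  # a sizable share of streamlines resolves a branch
  # mirror symmetry: conditional on resolving, each branch is equally likely
  expect_lt(abs(sum(h1) / n - 0.5), 3 * sqrt(0.25 / n))
})
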