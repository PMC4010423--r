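dims <- c(12L, 8L, 5L)

# voxel matrices as the integer form Streamline@voxels uses
im <- function(m) matrix(as.integer(m), ncol = 3L)

test_that("canonical streamline maximises pairwise voxel agreement", {
  A <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(5, 2, 2))
  B <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(5, 3, 2))
  C <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 3, 2), c(5, 4, 2))
  # |A^B| = 3, |A^C| = 2, |B^C| = 2 -> A scores 5, B scores 5, C scores 4;
  # tie between A and B broken by emission order -> A
  ss <- handSet(list(A, B, C), dims)
  expect_identical(unname(canonicalStreamline(ss)@voxels), im(A))

  # asymmetric case with a clear winner
  D <- rbind(c(2, 2, 2), c(3, 3, 2))        # |A^D| = 1
  ss2 <- handSet(list(C, A, B, D), dims)    # scores: C 4+2+1? compute below
  # pairwise overlaps: C-A 2, C-B 2, C-D 1; A-B 3, A-D 1; B-D 1
  # scores: C 5, A 6, B 6, D 3 -> tie A/B -> A (earlier index)
  expect_identical(unname(canonicalStreamline(ss2)@voxels), im(A))

  # all identical -> the first; single streamline -> itself
  ss3 <- handSet(list(A, A, A), dims)
  expect_identical(canonicalStreamline(ss3)@voxels[, 1], im(A)[, 1])
  ss4 <- handSet(list(C), dims)
  expect_identical(unname(canonicalStreamline(ss4)@voxels), im(C))
  expect_error(canonicalStreamline(handSet(list(), dims, nEmitted = 1L)),
               "no successful")
  # nUse limits the comparison to the leading streamlines
  ss5 <- handSet(list(D, A, B), dims)
  expect_identical(unname(canonicalStreamline(ss5, nUse = 1)@voxels), im(D))
})

test_that("profile extraction walks the LOI outward from the seed boundary", {
  seed <- Region(rbind(c(2, 2, 2), c(2, 3, 2)), dims = dims)
  loi <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(4, 3, 2), c(5, 3, 2))
  const <- array(0.3, dims)
  pr <- extractProfile(const, loi, seed)
  expect_equal(pr@distance, 0:4)
  expect_equal(pr@value, rep(0.3, 5))

  # a map equal to the distance from the seed along the bundle reproduces
  # the sample distances
  dmap <- array(0, dims)
  for (i in seq_len(nrow(loi)))
    dmap[loi[i, 1], loi[i, 2], loi[i, 3]] <- i - 1
  pr2 <- extractProfile(dmap, loi, seed)
  expect_equal(pr2@value, pr2@distance)

  # duplicate voxels collapse
  loiDup <- loi[c(1, 2, 2, 3, 4, 4, 5), ]
  pr3 <- extractProfile(const, loiDup, seed)
  expect_equal(pr3@distance, 0:4)

  # the longer side of a bidirectional LOI is profiled
  loi2 <- rbind(c(1, 2, 2), c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  pr4 <- extractProfile(const, loi2, seed)
  expect_equal(length(pr4@distance), 3)

  expect_error(extractProfile(const, rbind(c(9, 7, 4)), seed),
               "does not intersect")
})

test_that("linear compensation is a distance ramp, invertible for d >= 1", {
  pr <- TractProfile(distance = 0:5, value = rep(2, 6),
                     loiVoxels = matrix(0L, 6, 3))
  lc <- linearCompensation(pr)
  expect_equal(lc@value, c(2, 2, 4, 6, 8, 10))
  # invertibility for d >= 1
  expect_equal(lc@value[-1] / pmax(lc@distance[-1], 1), pr@value[-1])
  # zero profile stays zero
  z <- TractProfile(distance = 0:3, value = rep(0, 4),
                    loiVoxels = matrix(0L, 4, 3))
  expect_equal(linearCompensation(z)@value, rep(0, 4))
  # exponential decay: compensated profile peaks near d = 1/k, not flat
  k <- 0.25
  d <- 0:30
  ex <- TractProfile(distance = d, value = exp(-k * d),
                     loiVoxels = matrix(0L, 31, 3))
  lce <- linearCompensation(ex)
  expect_equal(lce@distance[which.max(lce@value)], 4)  # argmax of d e^(-kd)
  expect_gt(max(lce@value) / lce@value[length(d)], 2)  # still declining tail
})

test_that("decline statistic is the rank correlation with distance", {
  mk <- function(v) TractProfile(distance = seq_along(v) - 1, value = v,
                                 loiVoxels = matrix(0L, length(v), 3))
  expect_equal(declineStatistic(mk(c(5, 4, 3, 2, 1))), -1)
  expect_equal(declineStatistic(mk(c(1, 2, 3, 4, 5))), 1)
  expect_equal(declineStatistic(mk(rep(2, 5))), 0)
  v <- c(3, 1, 4, 1, 5)
  expect_equal(declineStatistic(mk(v)),
               cor(0:4, v, method = "spearman"))
  expect_error(declineStatistic(mk(c(1, 2))), ">= 3")
})

test_that("cross-section profile counts voxels per nearest centerline bin", {
  ph <- makeStraightBundle(10, radius = 2, dispersion = 0)
  cl <- ph@centerlines$bundle
  reg <- regionFromMask(ph@bundleMasks$bundle)
  cs <- crossSectionProfile(reg, cl)
  expect_identical(nrow(cs), nrow(cl))
  expect_identical(sum(cs$count), regionSize(reg))
  # interior bins of a constant-radius tube have identical counts
  inner <- cs$count[3:8]
  expect_true(all(inner == inner[1]))
  # region = centerline -> every bin counts exactly 1
  cs2 <- crossSectionProfile(Region(cl, dims = gridDims(ph)), cl)
  expect_true(all(cs2$count == 1L))
  # truncated region leaves empty distal bins
  half <- regionFromMask(ph@bundleMasks$bundle &
                         (slice.index(ph@bundleMasks$bundle, 1) < cl[5, 1]))
  cs3 <- crossSectionProfile(half, cl)
  expect_true(all(cs3$count[7:10] == 0L))
})

test_that("flare metric is the near-seed false-positive fraction", {
  seed <- Region(rbind(c(2, 2, 2)), dims = dims)
  bundle <- array(FALSE, dims)
  bundle[2:9, 2, 2] <- TRUE
  # region inside the bundle -> no flare
  expect_equal(flareMetric(regionFromMask(bundle), seed, bundle, 3), 0)
  # near-seed ball fully outside the bundle -> flare 1
  ball <- array(FALSE, dims)
  ball[2:3, 3:4, 2] <- TRUE
  expect_equal(flareMetric(regionFromMask(ball), seed, bundle, 4), 1)
  # mixed hand-built case: 3 near voxels, 1 outside the bundle
  reg <- Region(rbind(c(3, 2, 2), c(4, 2, 2), c(3, 3, 2), c(9, 2, 2)),
                dims = dims)
  expect_equal(flareMetric(reg, seed, bundle, 2.5), 1 / 3)
  # far voxels are ignored entirely
  regFar <- Region(rbind(c(9, 6, 4)), dims = dims)
  expect_equal(flareMetric(regFar, seed, bundle, 2), 0)
})

test_that("Dice coefficient follows its closed form", {
  r1 <- Region(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(4, 1, 1)),
               dims = dims)
  r2 <- Region(rbind(c(3, 1, 1), c(4, 1, 1), c(5, 1, 1), c(6, 1, 1)),
               dims = dims)
  expect_equal(diceCoefficient(r1, r1), 1)
  expect_equal(diceCoefficient(r1, r2), 0.5)  # |a|=|b|=4, overlap 2
  disj <- Region(rbind(c(9, 5, 4)), dims = dims)
  expect_equal(diceCoefficient(r1, disj), 0)
  empty <- Region(matrix(integer(0), ncol = 3), dims = dims)
  expect_equal(diceCoefficient(empty, empty), 1)
  expect_equal(diceCoefficient(r1, empty), 0)
})

test_that("canonical choice is permutation-covariant up to ties", {
  A <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(5, 2, 2))
  B <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(5, 3, 2))
  C <- rbind(c(2, 2, 2), c(3, 3, 2), c(4, 4, 2))
  paths <- list(A, B, C)
  # B and A tie; under any ordering the winner is one of the tied pair and
  # has the maximal score
  score <- function(i, sel) sum(vapply(sel[-i], function(o)
    nrow(merge(as.data.frame(sel[[i]]), as.data.frame(o))), numeric(1L)))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    sel <- paths[perm]
    win <- canonicalStreamline(handSet(sel, dims))@voxels
    scores <- vapply(seq_along(sel), score, numeric(1L), sel = sel)
    wi <- which(vapply(sel, function(p) identical(unname(win), im(p)), logical(1L)))
    expect_equal(scores[wi], max(scores))
  }
})
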