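test_that("degenerate zero-radius bundle is exactly its centerline", {
  ph <- makeStraightBundle(length = 40, radius = 0, dispersion = 0)
  expect_equal(sum(ph@bundleMasks$bundle), 40)
  # all populations identical and equal to the axis
  v <- regionVoxels(regionFromMask(ph@bundleMasks$bundle))
  dirs <- t(apply(v, 1L, function(p) ph@field@dir1[p[1], p[2], p[3], ]))
  expect_true(all(apply(dirs, 1L, identical, c(1, 0, 0))))
  expect_equal(nrow(ph@centerlines$bundle), 40)
})

test_that("bundle mask matches the brute-force rasterization oracle", {
  ph <- makeStraightBundle(length = 12, radius = 2, dispersion = 0)
  cl <- ph@centerlines$bundle
  oracle <- oracleTubeMask(as.numeric(cl[1, ]), c(1, 0, 0), 12, 2,
                           gridDims(ph))
  expect_identical(ph@bundleMasks$bundle, oracle)

  ph2 <- makeCrossingPhantom(angle = 45, bundleLength = 13, radius = 1.5,
                             dispersion = 0)
  expect_identical(regionToMask(ph2@regions$crossing),
                   ph2@bundleMasks$bundle1 & ph2@bundleMasks$bundle2)
  o1 <- oracleTubeMask(as.numeric(ph2@centerlines$bundle1[1, ]), c(1, 0, 0),
                       13, 1.5, gridDims(ph2))
  expect_identical(ph2@bundleMasks$bundle1, o1)
})

test_that("phantom generation is deterministic and honors invariants", {
  a <- makeStraightBundle(20, radius = 1.5, dispersion = 15)
  b <- makeStraightBundle(20, radius = 1.5, dispersion = 15)
  expect_identical(a@field@dir1, b@field@dir1)
  expect_identical(a@bundleMasks, b@bundleMasks)
  expect_identical(a@centerlines, b@centerlines)

  phantoms <- list(list(ph = a, lens = c(bundle = 20)),
                   list(ph = makeCrossingPhantom(60, 15, 1, 10),
                        lens = c(bundle1 = 15, bundle2 = 15)),
                   list(ph = makeBranchingPhantom(8, 45, 1, 0, childLength = 8),
                        lens = c(trunk = 8, child1 = 9, child2 = 9)))
  for (case in phantoms) {
    ph <- case$ph
    f <- ph@field
    n <- prod(gridDims(ph))
    d1 <- matrix(f@dir1, n, 3L)
    norms <- sqrt(rowSums(d1^2))
    expect_true(all(abs(norms[f@npop >= 1L] - 1) < 1e-9))
    for (m in ph@bundleMasks) expect_true(all(f@mask[m]))
    for (r in ph@regions)
      expect_true(all(f@mask[regionToMask(r)]))
    # centerline arc length (voxel steps) covers the declared bundle length
    for (nm in names(ph@centerlines)) {
      cl <- ph@centerlines[[nm]]
      steps <- sum(sqrt(rowSums(diff(cl)^2)))
      expect_gte(steps, case$lens[[nm]] - 1 - 1e-9)
    }
  }
})

test_that("crossing voxels carry two populations, orthogonal at 90 degrees", {
  ph <- makeCrossingPhantom(angle = 90, bundleLength = 15, radius = 1,
                            dispersion = 0)
  cross <- regionVoxels(ph@regions$crossing)
  expect_gt(nrow(cross), 0)
  for (i in seq_len(nrow(cross))) {
    p <- cross[i, ]
    expect_identical(ph@field@npop[p[1], p[2], p[3]], 2L)
    ip <- sum(ph@field@dir1[p[1], p[2], p[3], ] *
              ph@field@dir2[p[1], p[2], p[3], ])
    expect_lt(abs(ip), 1e-9)
  }
  # background voxel outside both tubes: no populations, still in the mask
  bg <- which(!ph@bundleMasks$bundle1 & !ph@bundleMasks$bundle2)
  expect_true(all(ph@field@npop[bg] == 0L))
  expect_true(all(ph@field@mask[bg]))
})

test_that("branching phantom: two-population branch, angle 0 degenerates", {
  ph <- makeBranchingPhantom(branchDistance = 8, branchAngle = 45, radius = 1,
                             dispersion = 0, childLength = 8)
  br <- regionVoxels(ph@regions$branch)
  expect_gt(nrow(br), 0)
  for (i in seq_len(nrow(br)))
    expect_identical(ph@field@npop[br[i, 1], br[i, 2], br[i, 3]], 2L)
  # trunk and child volumes against the rasterization oracle
  clT <- ph@centerlines$trunk
  oT <- oracleTubeMask(as.numeric(clT[1, ]), c(1, 0, 0), 8, 1, gridDims(ph))
  expect_identical(ph@bundleMasks$trunk, oT)

  ph0 <- makeBranchingPhantom(branchDistance = 8, branchAngle = 0, radius = 1,
                              dispersion = 0, childLength = 8)
  expect_identical(ph0@bundleMasks$child1, ph0@bundleMasks$child2)
})

test_that("undersized grids are rejected, parameters validated", {
  expect_error(makeStraightBundle(40, radius = 2, gridShape = c(20, 9, 9)),
               "exceeds the grid")
  expect_error(makeStraightBundle(2, radius = 1), ">= 3")
  expect_error(makeCrossingPhantom(angle = 5, bundleLength = 15), "angle")
  expect_error(makeCrossingPhantom(angle = 95, bundleLength = 15), "angle")
  expect_error(makeBranchingPhantom(2, 45), "branchDistance")
})

test_that("phantom export/import round-trips through NIfTI + JSON", {
  ph <- makeCrossingPhantom(angle = 60, bundleLength = 11, radius = 1,
                            dispersion = 10)
  dir <- file.path(tempfile("phantom"), "out")
  exportPhantom(ph, dir)
  on.exit(unlink(dirname(dir), recursive = TRUE))
  ph2 <- importPhantom(dir)
  expect_identical(ph2@field@npop, ph@field@npop)
  expect_equal(ph2@field@dir1, ph@field@dir1, tolerance = 1e-6)
  expect_equal(ph2@field@disp1, ph@field@disp1, tolerance = 1e-6)
  expect_identical(ph2@bundleMasks$bundle1, ph@bundleMasks$bundle1)
  expect_identical(sort(names(ph2@regions)), sort(names(ph@regions)))
  expect_identical(regionToMask(ph2@regions$seed),
                   regionToMask(ph@regions$seed))
  expect_identical(unname(ph2@centerlines$bundle1),
                   unname(ph@centerlines$bundle1))
})
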