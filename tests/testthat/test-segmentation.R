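# Vesselness filtering, region growing, component cleanup.

test_that("vesselness of a constant volume is zero everywhere", {
  vol <- imageVolume(array(7, c(20, 20, 20)), spacing = 1)
  v <- vesselnessMultiscale(vol, frangiConfig(scales = c(1, 2)))
  expect_true(all(voxelData(v) == 0))
})

test_that("vesselness matches a brute-force Hessian oracle on a tube", {
  ras <- tube_volume(radius = 2, L = 60, margin = 26)
  vol <- ras$volume
  d <- dim(voxelData(vol))
  center <- round(d / 2)
  cfg <- frangiConfig(scales = 2, c = 2)
  v <- vesselnessMultiscale(vol, cfg)
  H <- hessian_oracle(voxelData(vol), 2, center)
  expect_equal(voxelData(v)[center[1], center[2], center[3]],
               frangi_oracle(H, c = 2), tolerance = 1e-6)
})

test_that("for a radius-2-voxel tube the matched scale is small and the response is tubular", {
  ras <- tube_volume(radius = 2, L = 60, margin = 26)
  vol <- ras$volume
  d <- dim(voxelData(vol))
  center <- round(d / 2)
  # scale selection: the gamma-normalized Hessian norm at the centerline
  # (from the brute-force oracle) peaks at a scale matched to the radius
  norms <- vapply(1:6, function(s)
    sqrt(sum(eigen(hessian_oracle(voxelData(vol), s, center),
                   symmetric = TRUE)$values^2)), numeric(1))
  expect_true(which.max(norms) %in% 1:3)
  # centerline response dominates the background by >= 10x
  v <- vesselnessMultiscale(vol, frangiConfig(c = 2))
  bg <- voxelData(v)[3, 3, center[3]]
  expect_gt(voxelData(v)[center[1], center[2], center[3]],
            10 * max(bg, 1e-12))
})

test_that("max-fused vesselness dominates every single-scale response", {
  ras <- tube_volume(radius = 3, n = 28, L = 20)
  cfg <- frangiConfig(scales = 1:4, c = 2)
  fused <- voxelData(vesselnessMultiscale(ras$volume, cfg))
  for (s in 1:4) {
    single <- voxelData(vesselnessAtScale(ras$volume, s, cfg))
    expect_true(all(fused >= single - 1e-12))
  }
})

test_that("vesselness is invariant to intensity offsets and equivariant to 90-degree rotations", {
  ras <- tube_volume(radius = 3, n = 26, L = 22)
  cfg <- frangiConfig(scales = c(1, 2), c = 2)
  v1 <- voxelData(vesselnessMultiscale(ras$volume, cfg))
  shifted <- imageVolume(voxelData(ras$volume) + 55, spacing = 1)
  v2 <- voxelData(vesselnessMultiscale(shifted, cfg))
  expect_equal(v1, v2, tolerance = 1e-10)
  rot <- function(a) aperm(a, c(3, 2, 1))  # swap x and z axes
  vol_r <- imageVolume(rot(voxelData(ras$volume)), spacing = 1)
  v3 <- voxelData(vesselnessMultiscale(vol_r, cfg))
  expect_equal(v3, rot(v1), tolerance = 1e-6)
})

test_that("region growing fills a uniform image and respects intensity steps", {
  vol <- imageVolume(array(50, c(16, 16, 16)), spacing = 1)
  m <- regionGrow(vol, matrix(c(8L, 8L, 8L), 1))
  expect_true(all(voxelData(m)))
  # two adjacent blocks at 100 and 90: 2% band from the 100 block excludes 90
  arr <- array(100, c(16, 16, 16))
  arr[9:16, , ] <- 90
  vol2 <- imageVolume(arr, spacing = 1)
  m2 <- regionGrow(vol2, matrix(c(4L, 8L, 8L), 1), tolerance = 0.02)
  expect_true(all(voxelData(m2)[1:8, , ]))
  expect_false(any(voxelData(m2)[9:16, , ]))
})

test_that("region growing equals the exhaustive fixed-point oracle and is idempotent", {
  ras <- tube_volume(radius = 3, n = 24, L = 20)
  vol <- ras$volume
  d <- dim(voxelData(vol))
  seeds <- matrix(as.integer(c(round(d[1] / 2), round(d[2] / 2),
                               round(d[3] / 2))), 1)
  m <- regionGrow(vol, seeds, tolerance = 0.02)
  oracle <- grow_oracle(voxelData(vol), seeds, 0.02)
  expect_identical(unname(voxelData(m)), unname(oracle))
  # idempotence: growing again on the mask-as-image reproduces the mask
  volm <- imageVolume(array(as.numeric(voxelData(m)) * 100 + 1, d), spacing = 1)
  m2 <- regionGrow(volm, seeds, tolerance = 0.02)
  expect_identical(voxelData(m2), voxelData(m))
})

test_that("region growing rejects bad seeds and warns on seeds-only result", {
  vol <- imageVolume(array(c(100, rep(0, 16^3 - 1)), c(16, 16, 16)))
  expect_error(regionGrow(vol, matrix(c(99L, 1L, 1L), 1)), "out of bounds")
  expect_warning(regionGrow(vol, matrix(c(1L, 1L, 1L), 1)), "seeds-only")
})

test_that("component cleanup keeps the seeded component and drops floaters", {
  ras <- tube_volume(radius = 3, n = 24, L = 20)
  m <- voxelData(ras$truth)
  m[2:3, 2:3, 2:3] <- TRUE  # 8-voxel floater far from the tube
  d <- dim(m)
  seeds <- matrix(as.integer(c(round(d[1] / 2), round(d[2] / 2),
                               round(d[3] / 2))), 1)
  mask <- new("SegmentationMask", mask = m, spacing = 1, origin = c(0, 0, 0),
              seeds = seeds)
  cleaned <- cleanComponents(mask)
  expect_false(any(voxelData(cleaned)[2:3, 2:3, 2:3]))
  expect_identical(voxelData(cleaned) | FALSE, unname(voxelData(ras$truth)) | FALSE)
  # single component: unchanged
  mask2 <- new("SegmentationMask", mask = voxelData(ras$truth), spacing = 1,
               origin = c(0, 0, 0), seeds = seeds)
  expect_identical(voxelData(cleanComponents(mask2)), voxelData(mask2))
  # no component contains a seed
  far <- new("SegmentationMask", mask = m, spacing = 1, origin = c(0, 0, 0),
             seeds = matrix(c(1L, 10L, 10L), 1))
  expect_error(cleanComponents(far), "no connected component")
})
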