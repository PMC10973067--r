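# Isosurface extraction, mesh smoothing, cleanup, end cutting and extrusion.

test_that("a single padded voxel yields a small closed topological sphere", {
  m <- array(FALSE, c(16, 16, 16))
  m[8, 8, 8] <- TRUE
  mask <- new("SegmentationMask", mask = m, spacing = 1, origin = c(0, 0, 0),
              seeds = matrix(c(8L, 8L, 8L), 1))
  mesh <- extractSurface(mask, smoothSigma = 0)
  expect_true(meshIsClosed(mesh))
  nE <- nrow(unique(cowflow:::.mesh_edge_df(mesh)))
  euler <- nrow(meshVertices(mesh)) - nE + nrow(meshTriangles(mesh))
  expect_equal(euler, 2)
})

test_that("digitized ball surface area is near-analytic after smoothing", {
  mesh <- extractSurface(ball_mask(r = 8, n = 32))
  expect_true(meshIsClosed(mesh))
  smoothed <- smoothSurface(mesh, 10, 0.5)
  expect_lt(abs(meshArea(smoothed) - 4 * pi * 64) / (4 * pi * 64), 0.05)
  expect_lt(abs(meshVolume(mesh) - 4 / 3 * pi * 512) / (4 / 3 * pi * 512), 0.05)
})

test_that("tube phantom surfaces are watertight", {
  ras <- tube_volume(radius = 4, n = 30, L = 26)
  mask <- new("SegmentationMask", mask = voxelData(ras$truth), spacing = 1,
              origin = voxelOrigin(ras$truth), seeds = matrix(1L, 1, 3))
  mesh <- extractSurface(mask)
  ed <- cowflow:::.mesh_edge_df(mesh)
  cnt <- table(paste(ed$a, ed$b))
  expect_true(all(cnt == 2))
})

test_that("surface extraction demands padding", {
  m <- array(TRUE, c(16, 16, 16))
  mask <- new("SegmentationMask", mask = m, spacing = 1, origin = c(0, 0, 0),
              seeds = matrix(c(8L, 8L, 8L), 1))
  expect_error(extractSurface(mask), "pad")
})

test_that("Laplacian smoothing is the identity at 0 iterations and shrinks convex bodies", {
  mesh <- extractSurface(ball_mask(r = 6, n = 24))
  expect_identical(smoothSurface(mesh, 0, 0.5), mesh)
  expect_error(smoothSurface(mesh, 5, 0), "step")
  v <- meshVolume(mesh)
  m2 <- mesh
  for (i in 1:10) {
    m2 <- smoothSurface(m2, 1, 0.5)
    v2 <- meshVolume(m2)
    expect_lt(v2, v)
    v <- v2
  }
  expect_identical(meshTriangles(m2), meshTriangles(mesh))
})

test_that("smoothing a tube mesh does not displace vertices by more than the radius", {
  ras <- tube_volume(radius = 4, n = 30, L = 26)
  mask <- new("SegmentationMask", mask = voxelData(ras$truth), spacing = 1,
              origin = voxelOrigin(ras$truth), seeds = matrix(1L, 1, 3))
  mesh <- extractSurface(mask)
  sm <- smoothSurface(mesh, 20, 0.5)
  disp <- sqrt(rowSums((meshVertices(sm) - meshVertices(mesh))^2))
  expect_lt(max(disp), 4)
})

test_that("mesh cleanup keeps the largest-area component", {
  mesh1 <- extractSurface(ball_mask(r = 7, n = 32))
  m <- array(FALSE, c(16, 16, 16)); m[8, 8, 8] <- TRUE
  mesh2 <- extractSurface(new("SegmentationMask", mask = m, spacing = 1,
                              origin = c(100, 100, 100),
                              seeds = matrix(c(8L, 8L, 8L), 1)),
                          smoothSigma = 0)
  combined <- new("SurfaceMesh",
                  vertices = rbind(meshVertices(mesh1), meshVertices(mesh2)),
                  triangles = rbind(meshTriangles(mesh1),
                                    meshTriangles(mesh2) + nrow(meshVertices(mesh1))),
                  openings = cowflow:::.empty_openings())
  cleaned <- cleanComponents(combined)
  expect_equal(nrow(meshTriangles(cleaned)), nrow(meshTriangles(mesh1)))
})

test_that("perpendicular cuts recover the tube cross-section and extrude cleanly", {
  # radius 8 voxels: grey-level isosurface of the partial-volume field
  net <- tube_network(radius = 4, len = 40)
  ras <- rasterizeNetwork(net, spacing = 0.5, seed = 1, margin = 6)
  mesh <- extractSurface(ras$volume, isoLevel = 50)
  ends <- data.frame(label = c("in", "out"), kind = c("inlet", "outlet"),
                     x = c(6, 34), y = 16, z = 16, nx = c(-1, 1), ny = 0,
                     nz = 0, radius = 4)
  cut <- cutAndExtrudeEnds(mesh, ends, extrusionLength = 3)
  op <- meshOpenings(cut)
  expect_equal(nrow(op), 2)
  expect_lt(max(abs(op$area_mm2 - pi * 16)) / (pi * 16), 0.03)
  expect_equal(length(meshBoundaryLoops(cut)), 2)
  # zero-length extrusion adds no vertices beyond the cut loops
  cut0 <- cutAndExtrudeEnds(mesh, ends, extrusionLength = 0)
  expect_lt(nrow(meshVertices(cut0)), nrow(meshVertices(cut)))
  expect_equal(length(meshBoundaryLoops(cut0)), 2)
  # a plane that misses the mesh is reported with the end label
  bad <- data.frame(label = "ghost", kind = "outlet", x = 200, y = 200,
                    z = 200, nx = 1, ny = 0, nz = 0, radius = 2)
  expect_error(cutAndExtrudeEnds(mesh, bad), "ghost")
})

test_that("a CoW phantom cut at 3 inlets and 10 outlets has 13 boundary loops", {
  net <- generateCowTemplate(nOutlets = 10, seed = 5)
  ras <- rasterizeNetwork(net, spacing = 0.32, seed = 1, maxVoxels = 280^3)
  mesh <- extractSurface(ras$volume, isoLevel = 50)
  ends <- openingsFromNetwork(net)
  # cut 1 mm inside the capsule ends
  ends$x <- ends$x - ends$nx; ends$y <- ends$y - ends$ny
  ends$z <- ends$z - ends$nz
  cut <- cutAndExtrudeEnds(mesh, ends, extrusionLength = 2)
  expect_equal(length(meshBoundaryLoops(cut)), 13)
  # opening-area bookkeeping per inlet branch within 10% of network truth
  op <- meshOpenings(cut)
  expect_equal(nrow(op), 13)
  truth <- pi * ends$radius^2
  expect_lt(max(abs(op$area_mm2 - truth) / truth), 0.10)
})
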