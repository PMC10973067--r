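# Centerline network extraction, outlet prominence, trimming, aneurysm
# attachment.

test_that("a straight tube skeletonizes to two nodes and one edge with the true radius", {
  ras <- tube_volume(radius = 4, n = 30, L = 40)
  mask <- new("SegmentationMask", mask = voxelData(ras$truth), spacing = 1,
              origin = voxelOrigin(ras$truth), seeds = matrix(1L, 1, 3))
  net <- skeletonizeNetwork(mask)
  expect_equal(nrow(networkNodes(net)), 2)
  expect_equal(nrow(networkEdges(net)), 1)
  expect_lt(abs(networkEdges(net)$radius - 4), 0.5)
})

test_that("a Y bifurcation skeletonizes to one junction, three ends, three edges", {
  nodes <- data.frame(id = c("in", "j", "o1", "o2"),
                      x = c(0, 15, 30, 30), y = c(0, 0, 10, -10), z = 0,
                      kind = c("inlet", "junction", "outlet", "outlet"),
                      label = c("IN", "j", "o1", "o2"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = c("e0", "e1", "e2"),
                      from = c("in", "j", "j"), to = c("j", "o1", "o2"),
                      length = c(15, sqrt(225 + 100), sqrt(225 + 100)),
                      radius = c(3, 2.4, 2.4), kind = "vessel",
                      stringsAsFactors = FALSE)
  y <- vesselNetwork(nodes, edges)
  ras <- rasterizeNetwork(y, spacing = 1, seed = 1, margin = 6)
  mask <- new("SegmentationMask", mask = voxelData(ras$truth), spacing = 1,
              origin = voxelOrigin(ras$truth), seeds = matrix(1L, 1, 3))
  net <- skeletonizeNetwork(mask)
  deg <- table(factor(c(networkEdges(net)$from, networkEdges(net)$to),
                      levels = networkNodes(net)$id))
  expect_equal(nrow(networkNodes(net)), 4)
  expect_equal(nrow(networkEdges(net)), 3)
  expect_equal(sort(as.integer(deg)), c(1, 1, 1, 3))
})

test_that("a CoW phantom's inlets and outlets are all recovered and labelled", {
  net <- generateCowTemplate(nOutlets = 10, seed = 2)
  ras <- rasterizeNetwork(net, spacing = 0.32, seed = 1, maxVoxels = 280^3)
  seeds <- round(worldToVoxel(ras$volume,
                              as.matrix(inletNodes(net)[, c("x", "y", "z")])))
  seg <- segmentVolume(ras$volume, seeds)
  rec <- skeletonizeNetwork(seg, openings = openingsFromNetwork(net))
  expect_equal(nrow(inletNodes(rec)), 3)
  expect_equal(nrow(outletNodes(rec)), 10)
  expect_setequal(inletNodes(rec)$label, c("ICAl", "ICAr", "BA"))
})

test_that("outlet prominence sorts by area with deterministic tie-breaks", {
  tn <- trunk_network(nSide = 2, sideRadius = 1.0)
  # radii: sides 1.0, main trunk 1.5
  p <- outletProminence(tn)
  expect_equal(p$id[1], "out")
  expect_equal(p$area_mm2, pi * c(1.5, 1, 1)^2)
  expect_equal(p$id[-1], sort(p$id[-1]))  # equal areas: label order
  # permutation property: same outlet multiset in and out
  expect_setequal(p$id, outletNodes(tn)$id)
})

test_that("trimming keeps inlets, prunes dangling chains and preserves kept geometry", {
  net <- generateCowTemplate(nOutlets = 20, seed = 3)
  trimmed <- trimNetwork(net, 10)
  expect_equal(nrow(outletNodes(trimmed)), 10)
  expect_equal(nrow(inletNodes(trimmed)), 3)
  expect_true(validObject(trimmed))
  # geometry on kept paths identical: inlet->outlet path length and min
  # radius agree between models
  g1 <- cowflow:::.as_igraph(net)
  g2 <- cowflow:::.as_igraph(trimmed)
  for (out in outletNodes(trimmed)$id) {
    d1 <- igraph::distances(g1, "ICAr.in", out,
                            weights = networkEdges(net)$length)
    d2 <- igraph::distances(g2, "ICAr.in", out,
                            weights = networkEdges(trimmed)$length)
    expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
  }
})

test_that("trimming to all outlets is the identity up to degree-2 merging", {
  net <- generateCowTemplate(nOutlets = 12, seed = 4)
  all_out <- outletNodes(net)$id
  trimmed <- trimNetwork(net, all_out)
  merged <- mergeDegreeTwo(net)
  expect_setequal(networkNodes(trimmed)$id, networkNodes(merged)$id)
  expect_equal(sum(networkEdges(trimmed)$length),
               sum(networkEdges(merged)$length), tolerance = 1e-9)
})

test_that("trimming a trunk to its distal outlet prunes all side branches", {
  tn <- trunk_network(nSide = 3)
  trimmed <- trimNetwork(tn, "out")
  # reachability oracle: only nodes on the in->out path survive
  expect_setequal(networkNodes(trimmed)$id, c("in", "out"))
  expect_equal(nrow(networkEdges(trimmed)), 1)
  expect_equal(networkEdges(trimmed)$length, 40)
  # merged radius is the length-weighted mean (uniform here)
  expect_equal(networkEdges(trimmed)$radius, 1.5)
  expect_error(trimNetwork(tn, 99), "between 1 and")
})

test_that("aneurysm attachment splits the edge and detachment restores the network", {
  tn <- trunk_network(nSide = 2)
  spec <- makeAneurysmSpec(tn, "t1", arcPosition = 0.5, label = "IA-X")
  net2 <- attachAneurysm(tn, spec)
  expect_equal(nrow(networkEdges(net2)), nrow(networkEdges(tn)) + 2)
  expect_equal(nrow(networkNodes(net2)), nrow(networkNodes(tn)) + 2)
  sac <- networkNodes(net2)[networkNodes(net2)$kind == "aneurysm_sac", ]
  expect_equal(sac$label, "IA-X")
  expect_equal(sac$sac_volume_mm3, 100)
  # neck edge carries the neck radius
  neck <- networkEdges(net2)[networkEdges(net2)$kind == "neck", ]
  expect_equal(neck$radius, spec@neckRadius)
  expect_error(makeAneurysmSpec(net2, neck$id), "neck")
  # snapping near an endpoint warns
  spec0 <- makeAneurysmSpec(tn, "t1", arcPosition = 0.001)
  expect_warning(attachAneurysm(tn, spec0), "snap")
  # detach restores an isomorphic network
  back <- detachAneurysm(net2, "IA-X")
  expect_setequal(networkNodes(back)$kind, networkNodes(mergeDegreeTwo(tn))$kind)
  expect_equal(sum(networkEdges(back)$length), sum(networkEdges(tn)$length),
               tolerance = 1e-9)
  expect_equal(sort(table(c(networkEdges(back)$from, networkEdges(back)$to))),
               sort(table(c(networkEdges(mergeDegreeTwo(tn))$from,
                            networkEdges(mergeDegreeTwo(tn))$to))),
               ignore_attr = TRUE)
})

test_that("a sac survives trimming when its parent path is kept", {
  net <- generateCowTemplate(nOutlets = 20, seed = 6)
  ed <- networkEdges(net)
  mca <- ed$id[ed$label == "MCA.r"][1]
  net2 <- attachAneurysm(net, makeAneurysmSpec(net, mca, label = "IA-A"))
  trimmed <- trimNetwork(net2, 10)
  expect_equal(sum(networkNodes(trimmed)$kind == "aneurysm_sac"), 1)
})

test_that("branch summary reports per-branch outlet counts and areas", {
  net <- generateCowTemplate(nOutlets = 24, seed = 1)
  trimmed <- trimNetwork(net, 10)
  bs <- branchSummary(net, trimmed)
  expect_setequal(bs$branch, c("ICAr", "ICAl", "BA"))
  expect_equal(sum(bs$n_outlets_complex), 24)
  expect_equal(sum(bs$n_outlets_trimmed), 10)
  expect_true(all(bs$sum_area_trimmed_mm2 <= bs$sum_area_complex_mm2 + 1e-9))
})
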