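# Synthetic phantom generators: CoW template, rasterization, waveforms,
# aneurysm specifications.

test_that("CoW template has 3 labelled inlets, the requested outlets and a loop", {
  for (n in c(4, 10, 60)) {
    net <- generateCowTemplate(nOutlets = n, seed = 1)
    expect_s4_class(net, "VesselNetwork")
    inl <- inletNodes(net)
    expect_equal(nrow(inl), 3)
    expect_setequal(inl$label, c("ICAl", "ICAr", "BA"))
    expect_equal(nrow(outletNodes(net)), n)
    g <- igraph::graph_from_data_frame(
      networkEdges(net)[, c("from", "to")], directed = FALSE)
    expect_gte(igraph::ecount(g) - igraph::vcount(g) + 1, 1)  # cycle rank
  }
  expect_error(generateCowTemplate(nOutlets = 3), "nOutlets")
})

test_that("CoW template is deterministic in (nOutlets, seed) and labels trunks", {
  a <- generateCowTemplate(12, seed = 7)
  b <- generateCowTemplate(12, seed = 7)
  expect_identical(networkNodes(a), networkNodes(b))
  expect_identical(networkEdges(a), networkEdges(b))
  c2 <- generateCowTemplate(12, seed = 8)
  expect_false(identical(networkNodes(a), networkNodes(c2)))
  lab <- networkEdges(a)$label
  for (trunk in c("MCA.r", "MCA.l", "ACA.r", "ACA.l", "PCA.r", "PCA.l"))
    expect_true(any(lab == trunk))
})

test_that("unclamped template bifurcations satisfy the cube-law branching rule", {
  net <- generateCowTemplate(30, seed = 2, minRadius = 0.1)
  ed <- networkEdges(net)
  nd <- networkNodes(net)
  checked <- 0
  for (j in nd$id[nd$kind == "junction" & grepl("\\.j\\d+$", nd$id)]) {
    parent <- ed[ed$to == j, ]
    children <- ed[ed$from == j, ]
    if (nrow(parent) != 1 || nrow(children) != 2) next
    # taper-floored trunks break the rule by design; skip those
    if (any(children$radius <= 0.75 * max(parent$radius) + 1e-9 &
            children$label %in% c("MCA.r", "MCA.l", "ACA.r", "ACA.l",
                                  "PCA.r", "PCA.l"))) next
    expect_equal(parent$radius^3, sum(children$radius^3), tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("rasterized tube matches the analytic cylinder cross-section", {
  ras <- tube_volume(radius = 5, n = 40, L = 40)
  gt <- ras$truth
  m <- voxelData(gt)
  # interior slab away from the capsule caps: per-slice area ~ pi r^2
  zidx <- round(dim(m)[3] / 2) + (-5:5)
  areas <- apply(m[, , zidx], 3, sum)
  expect_lt(max(abs(areas - pi * 25)) / (pi * 25), 0.05)
})

test_that("noise-free rasterization mixes only lumen and background", {
  ras <- tube_volume(radius = 4, lumen = 100, background = 0)
  v <- voxelData(ras$volume)
  expect_gte(min(v), 0)
  expect_lte(max(v), 100)
  # partial-volume values exist strictly between the two levels
  expect_gt(sum(v > 1 & v < 99), 0)
})

test_that("rasterization is deterministic and honors the voxel budget", {
  net <- tube_network(radius = 3, len = 30)
  a <- rasterizeNetwork(net, spacing = 1, noiseSd = 5, seed = 42)
  b <- rasterizeNetwork(net, spacing = 1, noiseSd = 5, seed = 42)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  c2 <- rasterizeNetwork(net, spacing = 1, noiseSd = 5, seed = 43)
  expect_false(identical(voxelData(a$volume), voxelData(c2$volume)))
  expect_error(rasterizeNetwork(net, spacing = 0.05), "budget")
})

test_that("ground truth centerlines lie inside the ground truth mask", {
  ras <- tube_volume(radius = 4)
  gt <- ras$truth
  for (cl in gt@centerlines) {
    vox <- round(worldToVoxel(gt, cl))
    expect_true(all(voxelData(gt)[vox]))
  }
})

test_that("inflow waveform conserves its mean and respects the pulsatility floor", {
  for (p in c(0, 0.2, 0.5, 0.9)) {
    wf <- generateInflowWaveform(3.434e-3, period = 0.9, pulsatility = p,
                                 nSamples = 181)
    f <- waveformFlow(wf)
    tt <- waveformTime(wf)
    expect_equal(f[1], f[length(f)])
    # trapezoidal integral oracle
    integral <- sum((head(f, -1) + tail(f, -1)) / 2 * diff(tt))
    expect_equal(integral / 0.9, 3.434e-3, tolerance = 1e-9)
    expect_equal(min(f), 3.434e-3 * (1 - p), tolerance = 1e-6)
    if (p == 0) expect_true(all(f == 3.434e-3))
  }
  expect_error(generateInflowWaveform(1e-3, pulsatility = 1), "pulsatility")
  expect_error(generateInflowWaveform(-1), "meanFlow")
})

test_that("default CoW inflows carry the measured per-inlet means", {
  wfs <- cowInflows()
  expect_equal(meanFlow(wfs$ICAr), 3.434e-3, tolerance = 1e-9)
  expect_equal(meanFlow(wfs$ICAl), 3.065e-3, tolerance = 1e-9)
  expect_equal(meanFlow(wfs$BA), 2.332e-3, tolerance = 1e-9)
})

test_that("aneurysm specs scale the neck to the parent vessel", {
  net <- generateCowTemplate(10, seed = 1)
  ed <- networkEdges(net)
  mca <- ed$id[ed$label == "MCA.r"][1]
  spec <- makeAneurysmSpec(net, mca, neckRatio = 1.0)
  expect_equal(spec@neckRadius, ed$radius[ed$id == mca])
  spec2 <- makeAneurysmSpec(net, mca, neckRatio = 0.5)
  expect_equal(spec2@neckRadius, 0.5 * ed$radius[ed$id == mca])
  expect_error(makeAneurysmSpec(net, mca, sacVolume = -1), "sac volume")
  expect_error(makeAneurysmSpec(net, "nonsense"), "does not exist")
  # both MCA edges accept a spec, mirroring one sac per side
  mcal <- ed$id[ed$label == "MCA.l"][1]
  specA <- makeAneurysmSpec(net, mca, label = "IA-A")
  specB <- makeAneurysmSpec(net, mcal, label = "IA-B")
  net2 <- attachAneurysm(attachAneurysm(net, specA), specB)
  expect_equal(sum(networkNodes(net2)$kind == "aneurysm_sac"), 2)
})
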