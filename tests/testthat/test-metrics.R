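# Hemodynamic metrics: TAWSS, OSI, NIR, normalized profiles, centerline
# velocity curves, model comparison.

test_that("TAWSS matches analytic means", {
  t <- (0:9999) / 10000
  expect_equal(tawss(rep(2, 100)), 2)
  expect_equal(tawss(sin(2 * pi * t)), 2 / pi, tolerance = 1e-4)
  expect_equal(tawss(rep(0, 100)), 0)
  expect_error(tawss(numeric(0)), "empty")
})

test_that("OSI follows the standard oscillatory-shear definition", {
  t <- (0:9999) / 10000
  expect_equal(osi(sin(2 * pi * t)), 0.5, tolerance = 1e-6)
  expect_equal(osi(1 + sin(2 * pi * t)), 0)     # never reverses
  expect_equal(osi(abs(sin(2 * pi * t)) + 0.1), 0)
  expect_gte(osi(c(-1, 1, -1, 1)), 0)
  expect_warning(z <- osi(rep(0, 100)), "zero")
  expect_equal(z, 0)
  # phase invariance of the period metrics
  tau <- 0.3 + sin(2 * pi * t) + 0.4 * cos(4 * pi * t)
  for (k in c(17, 500, 9000)) {
    shifted <- c(tau[-(1:k)], tau[1:k])
    expect_equal(tawss(shifted), tawss(tau), tolerance = 1e-9)
    expect_equal(osi(shifted), osi(tau), tolerance = 1e-9)
    expect_equal(nir(shifted * 1e-6)$mean_mls, nir(tau * 1e-6)$mean_mls,
                 tolerance = 1e-9)
  }
})

test_that("NIR is the positive neck flow in ml/s", {
  t <- (0:9999) / 10000
  expect_equal(nir(rep(1e-7, 50))$mean_mls, 0.1)
  expect_equal(nir(1e-6 * sin(2 * pi * t))$mean_mls, 1 / pi,
               tolerance = 1e-4)
  expect_true(all(nir(-abs(rnorm(100)))$series_mls == 0))
  expect_true(all(nir(1e-6 * sin(2 * pi * t))$series_mls >= 0))
})

test_that("velocity normalization scales the plane mean to one", {
  Q <- rep(1e-6, 64)
  ps <- womersleyProfile(Q, period = 1, radius = 1e-3)
  vn <- vNorm(ps)
  A <- sum(ps@weights)
  expect_equal(as.numeric(ps@weights %*% vn / A), rep(1, 64),
               tolerance = 1e-3)
  expect_equal(max(vn[, 1]), 2, tolerance = 1e-3)  # parabolic peak/mean
  # uniform profile: V = Q/A everywhere gives V_norm = 1
  uni <- new("PlaneSample", radius = 1e-3, r = ps@r, weights = ps@weights,
             velocity = matrix(1e-6 / A, length(ps@r), 4),
             Q = rep(1e-6, 4), time = (0:3) / 4)
  expect_true(all(abs(vNorm(uni) - 1) < 1e-12))
  # zero flow: error, or NA with a warning in batch mode
  zero <- uni; zero@Q[2] <- 0
  expect_error(vNorm(zero), "undefined")
  expect_warning(vz <- vNorm(zero, skipZero = TRUE), "zero")
  expect_true(all(is.na(vz[, 2])))
})

test_that("spatial-mean normalization leaves mean one and rejects zero means", {
  expect_equal(normalizeBySpatialMean(rep(4, 10)), rep(1, 10))
  expect_equal(normalizeBySpatialMean(c(1, 3)), c(0.5, 1.5))
  set.seed(1)
  x <- rlnorm(500)
  expect_equal(mean(normalizeBySpatialMean(x)), 1, tolerance = 1e-12)
  expect_error(normalizeBySpatialMean(c(-1, 1)), "zero")
})

test_that("centerline velocity reflects conservation across offtakes", {
  tube <- tube_network(radius = 1, len = 10)
  res <- solveUnsteady(tube, list(`in` = generateInflowWaveform(1e-3, 1, 0)),
                       config = solverConfig(cycles = 1))
  cv <- centerlineVelocity(res, tube, c("a", "b"), nPoints = 10)
  expect_equal(cv$velocity_m_s, rep(1e-6 / (pi * 1e-6), 10))
  expect_error(centerlineVelocity(res, tube, c("b", "a")), "inlet")
  # trunk with one side outlet taking 40% of the flow (areas 2:3)
  nodes <- data.frame(id = c("in", "j", "s", "out"),
                      x = c(0, 10, 10, 20), y = c(0, 0, 8, 0), z = 0,
                      kind = c("inlet", "junction", "outlet", "outlet"),
                      label = c("IN", "j", "s", "main.out"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = c("t1", "se", "t2"),
                      from = c("in", "j", "j"), to = c("j", "s", "out"),
                      length = c(10, 8, 10),
                      radius = c(1, sqrt(2 / pi), sqrt(3 / pi)),
                      kind = "vessel", stringsAsFactors = FALSE)
  net <- vesselNetwork(nodes, edges)
  res2 <- solveUnsteady(net, list(IN = generateInflowWaveform(1e-3, 1, 0)),
                        config = solverConfig(cycles = 1))
  q <- edgeFlows(res2)
  expect_equal(unname(q["t2", 1] / q["t1", 1]), 0.6, tolerance = 1e-9)
  cv2 <- centerlineVelocity(res2, net, c("in", "j", "out"), nPoints = 21)
  expect_true(any(cv2$distal_to_offtake))
  expect_false(cv2$distal_to_offtake[1])
})

test_that("model comparison is zero on identical inputs and keeps the sign convention", {
  net <- generateCowTemplate(nOutlets = 10, seed = 1)
  ed <- networkEdges(net)
  net <- attachAneurysm(net, makeAneurysmSpec(
    net, ed$id[ed$label == "MCA.r"][1], label = "IA-A"))
  res <- solveUnsteady(net, cowInflows(nSamples = 101),
                       config = solverConfig(cycles = 2))
  m <- computeMetrics(res, caseId = "case")
  rep0 <- compareModels(m, m)
  expect_true(all(rep0@summary$delta == 0))
  expect_equal(rep0@maxAbsPathDiff, 0)
  # delta = complex - trimmed: lower complex NIR means negative delta
  m2 <- m
  m2@sacTable$nir_mean_mls <- m@sacTable$nir_mean_mls + 0.05
  repd <- compareModels(m, m2)
  d <- repd@summary[repd@summary$metric == "nir_mean_mls", "delta"]
  expect_equal(d, -0.05, tolerance = 1e-12)
  # unpaired sacs are reported by label
  m3 <- m
  m3@sacTable$label <- "IA-Z"
  names(m3@sacSeries) <- "IA-Z"
  expect_error(compareModels(m, m3), "IA-")
})
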