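# Reduced-order pulsatile solver: Murray splitting, Poiseuille resistance,
# nodal pressure solve, sacs.

test_that("Murray fractions reduce to area fractions at n = 2 and sum to 1", {
  expect_equal(murraySplitFractions(rep(2, 4)), rep(0.25, 4))
  expect_equal(murraySplitFractions(c(1, 3)), c(0.25, 0.75))
  expect_equal(murraySplitFractions(c(1, 1), n = 3), c(0.5, 0.5))
  expect_equal(murraySplitFractions(c(1, 4), n = 3), c(1 / 9, 8 / 9))
  f <- murraySplitFractions(runif(17, 0.1, 5))
  expect_identical(sum(f), 1)
  expect_error(murraySplitFractions(c(1, -2)), "> 0")
})

test_that("edge resistance follows the Poiseuille closed form", {
  expect_equal(edgeResistance(1e-3, 1e-2), 8 * 0.004 * 1e-2 / (pi * 1e-12),
               tolerance = 1e-12)
  expect_equal(edgeResistance(1e-3, 1e-2), 1.0186e8, tolerance = 1e-4)
  expect_equal(edgeResistance(2e-3, 1e-2) * 16, edgeResistance(1e-3, 1e-2))
  expect_error(edgeResistance(1e-3, 0), "length")
  expect_error(edgeResistance(0, 1e-2), "radius")
})

test_that("steady single-tube pressure drop matches 8 mu L Q / (pi r^4)", {
  tube <- tube_network(radius = 1, len = 10)
  inflow <- list(`in` = generateInflowWaveform(1e-3, 1, 0))  # 1e-6 m^3/s
  res <- solveUnsteady(tube, inflow, config = solverConfig(cycles = 1))
  dP <- nodePressures(res)["a", 1] - nodePressures(res)["b", 1]
  expect_equal(unname(dP), 1e-6 * edgeResistance(1e-3, 1e-2), tolerance = 1e-10)
  # wall shear is the Poiseuille value
  expect_equal(unname(edgeShear(res)["t", 1]), 4 * 0.004 * 1e-6 / (pi * 1e-9),
               tolerance = 1e-10)
})

test_that("a symmetric two-limb loop splits the flow exactly in half", {
  net <- loop_network()
  inflow <- list(IN = generateInflowWaveform(2e-3, 1, 0.4))
  res <- solveUnsteady(net, inflow, config = solverConfig(cycles = 1))
  q <- edgeFlows(res)
  expect_equal(q["limb1", ], q["limb2", ], tolerance = 1e-12)
  expect_equal(q["limb1", ], q["e_in", ] / 2, tolerance = 1e-12)
})

test_that("a Y tree distributes outflow by Murray area fractions", {
  nodes <- data.frame(id = c("in", "j", "o1", "o2"),
                      x = c(0, 10, 20, 20), y = c(0, 0, 5, -5), z = 0,
                      kind = c("inlet", "junction", "outlet", "outlet"),
                      label = c("IN", "j", "o1", "o2"),
                      stringsAsFactors = FALSE)
  # terminal radii chosen so outlet areas are 1 and 3 mm^2
  edges <- data.frame(id = c("e0", "e1", "e2"), from = c("in", "j", "j"),
                      to = c("j", "o1", "o2"),
                      length = c(10, sqrt(125), sqrt(125)),
                      radius = c(1.5, sqrt(1 / pi), sqrt(3 / pi)),
                      kind = "vessel", stringsAsFactors = FALSE)
  y <- vesselNetwork(nodes, edges)
  inflow <- list(IN = generateInflowWaveform(1e-3, 1, 0))  # 1 ml/s
  res <- solveUnsteady(y, inflow, config = solverConfig(cycles = 1))
  expect_equal(unname(edgeFlows(res)["e1", 1]), 0.25e-6, tolerance = 1e-9)
  expect_equal(unname(edgeFlows(res)["e2", 1]), 0.75e-6, tolerance = 1e-9)
})

test_that("interior-node conservation holds to solver precision", {
  net <- generateCowTemplate(nOutlets = 16, seed = 9)
  res <- solveUnsteady(net, cowInflows(nSamples = 101),
                       config = solverConfig(cycles = 1))
  expect_lt(res@residual, 1e-10 * max(abs(edgeFlows(res))))
})

test_that("flows match an independently coded dense resistor-network solve", {
  for (seed in 1:5) {
    set.seed(seed)
    nN <- sample(5:8, 1)
    # random connected graph: a spanning path plus extra chords
    from <- c(seq_len(nN - 1), sample(nN, 2))
    to <- c(seq_len(nN - 1) + 1, sample(nN, 2))
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    ids <- sprintf("n%d", seq_len(nN))
    kind <- rep("internal", nN)
    kind[1] <- "inlet"; kind[nN] <- "outlet"; kind[nN - 1] <- "outlet"
    nodes <- data.frame(id = ids, x = seq_len(nN) * 10, y = 0, z = 0,
                        kind = kind, label = ids, stringsAsFactors = FALSE)
    edges <- data.frame(id = sprintf("e%d", seq_along(from)),
                        from = ids[from], to = ids[to],
                        length = runif(length(from), 15, 30),
                        radius = runif(length(from), 0.5, 2),
                        kind = "vessel", stringsAsFactors = FALSE)
    # drop duplicate edges between the same pair to keep the oracle simple
    pairKey <- paste(pmin(from, to), pmax(from, to))
    edges <- edges[!duplicated(pairKey), ]
    deg <- table(factor(c(edges$from, edges$to), levels = ids))
    nodes$kind[nodes$kind != "inlet" & deg == 1] <- "outlet"
    if (any(deg[nodes$kind == "inlet"] != 1)) next
    nodes$kind[nodes$kind == "outlet" & deg != 1] <- "internal"
    if (sum(nodes$kind == "outlet") == 0) next
    net <- try(vesselNetwork(nodes, edges), silent = TRUE)
    if (inherits(net, "try-error")) next
    inflow <- setNames(list(generateInflowWaveform(1e-3, 1, 0)),
                       nodes$label[nodes$kind == "inlet"])
    res <- solveUnsteady(net, inflow, config = solverConfig(cycles = 1))
    ## dense oracle: base-R conductance matrix and solve()
    g <- 1 / edgeResistance(edges$radius * 1e-3, edges$length * 1e-3)
    L <- matrix(0, nN, nN, dimnames = list(ids, ids))
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]
      L[a, a] <- L[a, a] + g[i]; L[b, b] <- L[b, b] + g[i]
      L[a, b] <- L[a, b] - g[i]; L[b, a] <- L[b, a] - g[i]
    }
    outs <- nodes$id[nodes$kind == "outlet"]
    pr <- outletProminence(net)
    fr <- murraySplitFractions(setNames(pr$area_mm2, pr$id)[outs])
    b <- setNames(rep(0, nN), ids)
    b[nodes$id[nodes$kind == "inlet"]] <- 1e-6
    b[outs] <- b[outs] - fr * 1e-6
    ref <- outs[1]
    keepN <- setdiff(ids, ref)
    p <- setNames(rep(0, nN), ids)
    p[keepN] <- solve(L[keepN, keepN], b[keepN])
    qOracle <- g * (p[edges$from] - p[edges$to])
    expect_equal(unname(edgeFlows(res)[edges$id, 1]), unname(qOracle),
                 tolerance = 1e-9)
  }
})

test_that("sac dynamics reach a periodic steady state by the evaluated cycle", {
  tn <- trunk_network(nSide = 1)
  net <- attachAneurysm(tn, makeAneurysmSpec(tn, "t1", label = "IA"))
  inflow <- list(IN = generateInflowWaveform(3e-3, 1, 0.5))
  r2 <- solveUnsteady(net, inflow, config = solverConfig(cycles = 2))
  r3 <- solveUnsteady(net, inflow, config = solverConfig(cycles = 3))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(edgeFlows(r3) - edgeFlows(r2)) / rms(edgeFlows(r3)), 0.01)
  # neck flow balances sac charging: C dP/dt = Q_neck (implicit Euler)
  C <- 1e-12
  dt <- r3@config@dt
  dP <- diff(c(r3@sacPressures[1, 1], r3@sacPressures[1, ]))[-1]
  expect_equal(unname(r3@sacFlows[1, -1]), unname(C * dP / dt), tolerance = 1e-6)
})

test_that("the solver rejects inconsistent inputs", {
  tube <- tube_network()
  expect_error(solveUnsteady(tube, list(bogus = generateInflowWaveform(1e-3, 1, 0))),
               "no inflow")
  net <- generateCowTemplate(8, 1)
  bad <- cowInflows()
  bad$BA <- generateInflowWaveform(2.332e-3, period = 0.8)
  expect_error(solveUnsteady(net, bad), "period")
})
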