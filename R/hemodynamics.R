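## Reduced-order pulsatile hemodynamics on the vessel graph.

#' Murray's-law outlet flow fractions
#'
#' Each outlet receives the fraction \eqn{r_i^n / \sum_j r_j^n} of the flow,
#' with \eqn{r_i = \sqrt{a_i/\pi}} derived from the outlet area. For the
#' default exponent n = 2 this reduces to area fractions. The last fraction
#' is set to one minus the sum of the others so the fractions sum to 1
#' exactly.
#'
#' @param areas outlet cross-sectional areas (any consistent unit).
#' @param n Murray exponent (default 2).
#' @return numeric vector of fractions summing to exactly 1.
#' @examples
#' murraySplitFractions(c(1, 3))        # 0.25 0.75
#' murraySplitFractions(c(1, 4), n = 3) # 1/9 8/9
#' @export
murraySplitFractions <- function(areas, n = 2) {
  if (length(areas) == 0) stop("need at least one outlet area")
  if (any(areas <= 0)) stop("all outlet areas must be > 0")
  r <- sqrt(areas / pi)
  f <- r^n / sum(r^n)
  f[length(f)] <- 1 - sum(f[-length(f)])
  f
}

#' Poiseuille resistance of a cylindrical vessel segment
#'
#' @param radius vessel radius (m).
#' @param length segment length (m).
#' @param fluid a [FluidProperties-class].
#' @return hydraulic resistance 8 mu L / (pi r^4) in Pa s/m^3.
#' @examples
#' edgeResistance(1e-3, 1e-2)  # 1.0186e8
#' @export
edgeResistance <- function(radius, length, fluid = fluidProperties()) {
  if (any(radius <= 0)) stop("radius must be > 0")
  if (any(length <= 0)) stop("length must be > 0")
  8 * fluid@mu * length / (pi * radius^4)
}

# internal: assemble time-invariant system matrix and bookkeeping
.assemble_system <- function(network, fluid, config) {
  nd <- network@nodes
  ed <- network@edges
  nodeIds <- nd$id
  nN <- length(nodeIds)
  nodeIdx <- setNames(seq_len(nN), nodeIds)
  rm_m <- ed$radius * 1e-3   # mm -> m
  lm_m <- ed$length * 1e-3
  gcond <- 1 / edgeResistance(rm_m, lm_m, fluid)
  iFrom <- nodeIdx[ed$from]
  iTo <- nodeIdx[ed$to]
  ij <- rbind(cbind(iFrom, iFrom), cbind(iTo, iTo),
              cbind(iFrom, iTo), cbind(iTo, iFrom))
  xx <- c(gcond, gcond, -gcond, -gcond)
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = xx, dims = c(nN, nN))
  ## compliant sacs: add C/dt on the sac diagonal (implicit Euler)
  sacRows <- which(nd$kind == "aneurysm_sac")
  Cdt <- rep(0, nN)
  if (length(sacRows) > 0)
    Cdt[sacRows] <- nd$sac_compliance_m3_per_Pa[sacRows] / config@dt
  A <- A + Matrix::Diagonal(nN, Cdt)
  refId <- if (length(config@referenceNode) > 0) config@referenceNode else {
    out <- nd$id[nd$kind == "outlet"]
    if (length(out) > 0) out[1] else nd$id[1]
  }
  ref <- nodeIdx[[refId]]
  keep <- setdiff(seq_len(nN), ref)
  Ared <- A[keep, keep, drop = FALSE]
  fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Ared)),
                  error = function(e)
                    stop("singular system: network disconnected after trimming?"))
  list(nodeIdx = nodeIdx, gcond = gcond, iFrom = iFrom, iTo = iTo,
       Cdt = Cdt, sacRows = sacRows, ref = ref, keep = keep, fac = fac,
       nN = nN)
}

#' Solve pulsatile flow on a vessel network
#'
#' Reduced-order counterpart of a 3D finite-volume simulation: vessels are
#' Poiseuille resistors on the network graph, inlet flows follow the
#' prescribed waveforms, every outlet is assigned its Murray's-law fraction
#' of the total instantaneous inflow, and interior flows (including the
#' communicating-artery loops) follow from the nodal pressure solve
#' (weighted graph Laplacian with prescribed boundary flows and a zero
#' reference pressure). Aneurysm sacs are compliant chambers advanced by
#' implicit Euler through their neck resistance. The simulation runs
#' \code{config@cycles} cardiac cycles (default 3) at \code{config@dt}
#' (default 1 ms) from a zero-pressure initial sac state; only the final
#' cycle is returned. Per-edge wall shear is the Poiseuille value
#' \eqn{\tau = 4 \mu Q / (\pi r^3)}.
#'
#' @param network a [VesselNetwork-class] (geometry in mm).
#' @param inflows named list of [FlowWaveform-class], one per inlet, keyed
#'   by inlet label or node id (flows in l/s). All periods must agree.
#' @param fluid a [FluidProperties-class].
#' @param config a [SolverConfig-class].
#' @return A [SimulationResult-class]; flows in m^3/s, pressures in Pa
#'   relative to the reference node, shear in Pa.
#' @export
solveUnsteady <- function(network, inflows, fluid = fluidProperties(),
                          config = solverConfig()) {
  stopifnot(is(network, "VesselNetwork"))
  validObject(config)
  nd <- network@nodes
  inl <- nd[nd$kind == "inlet", , drop = FALSE]
  if (nrow(inl) == 0) stop("network has no inlet")
  ## map waveforms to inlet node ids (by label, falling back to id)
  wf <- list()
  for (i in seq_len(nrow(inl))) {
    key <- if (inl$label[i] %in% names(inflows)) inl$label[i] else inl$id[i]
    if (!key %in% names(inflows))
      stop(sprintf("no inflow waveform for inlet '%s'", inl$label[i]))
    wf[[inl$id[i]]] <- inflows[[key]]
  }
  periods <- vapply(wf, function(w) w@period, 0)
  if (max(periods) - min(periods) > 1e-12)
    stop("inlet waveform periods do not match")
  period <- periods[[1]]

  sys <- .assemble_system(network, fluid, config)
  out <- outletNodes(network)
  if (nrow(out) == 0) stop("network has no outlet")
  prom <- outletProminence(network)
  areas <- setNames(prom$area_mm2, prom$id)[out$id]

  if (config@splitMode == "global") {
    frac <- setNames(murraySplitFractions(areas, config@murrayN), out$id)
    branchOf <- NULL
  } else {
    branchOf <- .outlet_branches(network)
    frac <- numeric(0)
    for (b in unique(branchOf)) {
      ids <- names(branchOf)[branchOf == b]
      frac[ids] <- murraySplitFractions(areas[ids], config@murrayN)
    }
  }

  nSteps <- max(1L, as.integer(round(period / config@dt)))
  dt <- period / nSteps
  totalSteps <- nSteps * config@cycles
  evalStart <- totalSteps - nSteps
  nE <- nrow(network@edges)
  flows <- matrix(0, nE, nSteps, dimnames = list(network@edges$id, NULL))
  press <- matrix(0, sys$nN, nSteps, dimnames = list(nd$id, NULL))
  sacIds <- nd$id[sys$sacRows]
  sacP <- matrix(0, length(sacIds), nSteps, dimnames = list(sacIds, NULL))
  sacQ <- sacP
  ## neck edge serving each sac
  ed <- network@edges
  neckOf <- vapply(sacIds, function(s)
    which(ed$kind == "neck" & (ed$from == s | ed$to == s))[1], 0L)

  inletIdx <- sys$nodeIdx[inl$id]
  outletIdx <- sys$nodeIdx[out$id]
  b <- numeric(sys$nN)
  pOld <- numeric(sys$nN)
  residual <- 0
  interior <- which(!nd$kind %in% c("inlet", "outlet", "aneurysm_sac"))
  inc <- Matrix::sparseMatrix(
    i = c(sys$iFrom, sys$iTo), j = c(seq_len(nE), seq_len(nE)),
    x = c(rep(-1, nE), rep(1, nE)), dims = c(sys$nN, nE))

  for (step in seq_len(totalSteps)) {
    t <- (step - 1) * dt
    qin <- vapply(inl$id, function(id) evalWaveform(wf[[id]], t) * 1e-3, 0)
    Qtot <- sum(qin)
    b[] <- 0
    b[inletIdx] <- qin
    if (is.null(branchOf)) {
      b[outletIdx] <- b[outletIdx] - frac[out$id] * Qtot
    } else {
      inBr <- setNames(qin, inl$label)
      b[outletIdx] <- b[outletIdx] - frac[out$id] * inBr[branchOf[out$id]]
    }
    if (length(sys$sacRows) > 0)
      b[sys$sacRows] <- b[sys$sacRows] + sys$Cdt[sys$sacRows] * pOld[sys$sacRows]
    p <- numeric(sys$nN)
    p[sys$keep] <- as.numeric(Matrix::solve(sys$fac, b[sys$keep]))
    q <- sys$gcond * (p[sys$iFrom] - p[sys$iTo])
    if (step > evalStart) {
      k <- step - evalStart
      flows[, k] <- q
      press[, k] <- p
      if (length(sacIds) > 0) {
        sacP[, k] <- p[sys$sacRows]
        for (si in seq_along(sacIds)) {
          eN <- neckOf[si]
          sgn <- if (ed$to[eN] == sacIds[si]) 1 else -1
          sacQ[si, k] <- sgn * q[eN]
        }
      }
      if (length(interior) > 0) {
        res <- abs(as.numeric(inc %*% q) - b)[interior]
        residual <- max(residual, max(res))
      }
    }
    pOld <- p
  }
  rm_m <- ed$radius * 1e-3
  wss <- flows * (4 * fluid@mu) / (pi * rm_m^3)
  new("SimulationResult",
      time = (seq_len(nSteps) - 1) * dt,
      flows = flows, pressures = press, wss = wss,
      sacPressures = sacP, sacFlows = sacQ,
      network = network, config = config,
      residual = residual)
}
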