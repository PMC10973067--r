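## Hemodynamic evaluation metrics: normalized velocity profiles, TAWSS,
## OSI, neck inflow rate, centerline velocity curves.

# period integral of a uniformly sampled periodic series. If the first and
# last samples duplicate the period endpoint the trapezoidal rule is used;
# otherwise the samples tile the period and the mean is exact.
.period_mean <- function(x, time = NULL) {
  if (length(x) == 0) stop("empty series")
  if (!is.null(time) && length(time) == length(x) &&
      abs((time[length(time)] - time[1]) - 0) > 0) {
    dt <- diff(time)
    sum((head(x, -1) + tail(x, -1)) / 2 * dt) / (time[length(time)] - time[1])
  } else {
    mean(x)
  }
}

#' Time-averaged wall shear stress
#'
#' Time average of |tau(t)| over one period (trapezoidal rule on the stored
#' uniform grid).
#'
#' @param tau wall shear samples (Pa) covering exactly one period.
#' @param time optional sample times (s); if given, the first and last
#'   samples are treated as period endpoints and integrated trapezoidally.
#' @return TAWSS in Pa.
#' @export
tawss <- function(tau, time = NULL) {
  .period_mean(abs(tau), time)
}

#' Oscillatory shear index
#'
#' The standard definition \eqn{OSI = 0.5 (1 - |\int \tau dt| / \int |\tau|
#' dt)}: 0 for shear that never reverses, 0.5 for fully oscillatory
#' zero-mean shear.
#'
#' @inheritParams tawss
#' @return OSI in [0, 0.5].
#' @export
osi <- function(tau, time = NULL) {
  if (length(tau) == 0) stop("empty series")
  denom <- .period_mean(abs(tau), time)
  if (denom == 0) {
    warning("identically zero shear series; OSI defined as 0")
    return(0)
  }
  0.5 * (1 - abs(.period_mean(tau, time)) / denom)
}

#' Aneurysm neck inflow rate
#'
#' The positive part of the neck flow (flow entering the sac), in ml/s,
#' and its time average.
#'
#' @param qNeck neck flow series (m^3/s), positive into the sac, covering
#'   one period.
#' @param time optional sample times (s).
#' @return list(series_mls, mean_mls).
#' @export
nir <- function(qNeck, time = NULL) {
  series <- pmax(qNeck, 0) * 1e6  # m^3/s -> ml/s
  list(series_mls = series, mean_mls = .period_mean(series, time))
}

#' Normalized velocity profile on a cross-sectional plane
#'
#' Scales every sampled velocity by \eqn{A_{plane} / Q_{plane}} so that the
#' area-weighted plane mean is 1: \eqn{V_{Norm} = V A_{plane} / Q_{plane}}.
#'
#' @param plane a [PlaneSample-class].
#' @param skipZero in batch use, time samples with zero plane flow are
#'   returned as NA with a warning instead of an error.
#' @return matrix (radial x time) of normalized velocities.
#' @export
vNorm <- function(plane, skipZero = FALSE) {
  stopifnot(is(plane, "PlaneSample"))
  A <- sum(plane@weights)
  Q <- plane@Q
  zero <- Q == 0
  if (any(zero)) {
    if (!skipZero)
      stop("undefined normalization: plane flow is zero at some time sample")
    warning("plane flow is zero at some time samples; returning NA there")
  }
  out <- sweep(plane@velocity, 2, A / Q, "*")
  out[, zero] <- NA_real_
  out
}

#' Normalize a field by its spatial mean
#'
#' @param values numeric vector (field over a region).
#' @return values divided by their mean; the output mean is 1.
#' @export
normalizeBySpatialMean <- function(values) {
  if (length(values) == 0) stop("empty region")
  m <- mean(values)
  if (m == 0) stop("zero spatial mean: normalization undefined")
  values / m
}

#' Time-averaged centerline velocity along an inlet-rooted path
#'
#' Samples the time-averaged cross-section mean velocity
#' \eqn{\bar{Q} / (\pi r^2)} at equidistant arc-length stations along a
#' path of network edges starting at an inlet, and flags stations lying
#' immediately distal to junctions that carry off-path branches (where
#' outlet-related flow changes occur).
#'
#' @param result a [SimulationResult-class].
#' @param network the solved [VesselNetwork-class].
#' @param path character vector of node ids from an inlet to a distal node,
#'   or the result of [inletPaths()].
#' @param nPoints number of equidistant stations.
#' @return data.frame (arclength_mm, velocity_m_s, edge_id,
#'   distal_to_offtake).
#' @export
centerlineVelocity <- function(result, network, path, nPoints = 50) {
  nd <- network@nodes
  ed <- network@edges
  if (!path[1] %in% nd$id[nd$kind == "inlet"])
    stop("path must start at an inlet node")
  ## edges along the path
  eids <- character(length(path) - 1)
  for (i in seq_len(length(path) - 1)) {
    hit <- which((ed$from == path[i] & ed$to == path[i + 1]) |
                 (ed$to == path[i] & ed$from == path[i + 1]))
    if (length(hit) == 0)
      stop(sprintf("no edge between '%s' and '%s'", path[i], path[i + 1]))
    eids[i] <- ed$id[hit[1]]
  }
  lens <- ed$length[match(eids, ed$id)]
  radii <- ed$radius[match(eids, ed$id)] * 1e-3  # m
  qbar <- rowMeans(abs(result@flows[eids, , drop = FALSE]))
  vbar <- qbar / (pi * radii^2)
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  stations <- seq(0, total, length.out = nPoints)
  seg <- pmin(findInterval(stations, cum, rightmost.closed = TRUE), length(eids))
  ## a station is distal to an offtake if any path node before it has degree > 2
  deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
  nodeArc <- cum
  offtakeArcs <- nodeArc[which(deg[path] > 2)]
  data.frame(
    arclength_mm = stations,
    velocity_m_s = vbar[seg],
    edge_id = eids[seg],
    distal_to_offtake = vapply(stations, function(s)
      any(offtakeArcs <= s + 1e-9 & offtakeArcs > 1e-9), logical(1)))
}

#' Inlet-rooted centerline paths to selected outlets
#'
#' Shortest (by length) node paths from each inlet to the requested outlets.
#'
#' @param network a [VesselNetwork-class].
#' @param targets outlet node ids or labels; defaults to the main trunk
#'   outlets (labels ending in ".out") or, failing that, all outlets.
#' @return named list of node-id vectors.
#' @export
inletPaths <- function(network, targets = NULL) {
  nd <- network@nodes
  out <- nd[nd$kind == "outlet", , drop = FALSE]
  if (is.null(targets)) {
    main <- grepl("\\.out$", out$label)
    targets <- if (any(main)) out$id[main] else out$id
  } else {
    targets <- out$id[out$id %in% targets | out$label %in% targets]
  }
  g <- .as_igraph(network)
  inl <- nd[nd$kind == "inlet", , drop = FALSE]
  branch <- .outlet_branches(network)
  paths <- list()
  for (tid in targets) {
    b <- branch[[tid]]
    src <- inl$id[match(b, inl$label)]
    if (is.na(src)) src <- inl$id[1]
    sp <- igraph::shortest_paths(g, from = as.character(src),
                                 to = as.character(tid),
                                 weights = network@edges$length)
    nodePath <- names(sp$vpath[[1]])
    lab <- out$label[out$id == tid]
    paths[[paste0(inl$label[inl$id == src], "->", lab)]] <- nodePath
  }
  paths
}

#' Evaluate the full metric set for one simulation
#'
#' Computes per-edge TAWSS and OSI, per-sac neck inflow rate and
#' wall-shear surrogate series (the neck-edge Poiseuille shear, reported
#' as wss_proxy), and time-averaged centerline velocity curves along the
#' given paths.
#'
#' @param result a [SimulationResult-class].
#' @param paths named list of node-id paths (see [inletPaths()]); NULL
#'   computes the default trunk paths.
#' @param nPoints stations per centerline path.
#' @param caseId identifier stored in the output.
#' @return A [HemodynamicMetrics-class].
#' @export
computeMetrics <- function(result, paths = NULL, nPoints = 50,
                           caseId = "case") {
  network <- result@network
  nd <- network@nodes
  ed <- network@edges
  edgeTable <- data.frame(
    edge_id = ed$id,
    tawss_Pa = apply(result@wss, 1, tawss),
    osi = suppressWarnings(apply(result@wss, 1, osi)),
    mean_velocity_m_s = rowMeans(abs(result@flows)) /
      (pi * (ed$radius * 1e-3)^2),
    stringsAsFactors = FALSE)
  sacIds <- rownames(result@sacFlows)
  sacLabels <- nd$label[match(sacIds, nd$id)]
  sacTable <- data.frame(label = character(0), nir_mean_mls = numeric(0),
                         wss_proxy_mean_Pa = numeric(0),
                         wss_proxy_max_Pa = numeric(0), osi = numeric(0),
                         stringsAsFactors = FALSE)
  sacSeries <- list()
  for (i in seq_along(sacIds)) {
    neck <- which(ed$kind == "neck" &
                  (ed$from == sacIds[i] | ed$to == sacIds[i]))[1]
    tauN <- result@wss[neck, ]
    nirRes <- nir(result@sacFlows[i, ])
    sacTable <- rbind(sacTable, data.frame(
      label = sacLabels[i],
      nir_mean_mls = nirRes$mean_mls,
      wss_proxy_mean_Pa = tawss(tauN),
      wss_proxy_max_Pa = max(abs(tauN)),
      osi = suppressWarnings(osi(tauN)),
      stringsAsFactors = FALSE))
    sacSeries[[sacLabels[i]]] <- data.frame(
      time_s = result@time,
      nir_mls = nirRes$series_mls,
      wss_proxy_Pa = abs(tauN))
  }
  if (is.null(paths)) paths <- inletPaths(network)
  curves <- lapply(paths, function(p)
    centerlineVelocity(result, network, p, nPoints))
  new("HemodynamicMetrics", edgeTable = edgeTable, sacTable = sacTable,
      sacSeries = sacSeries, paths = curves, caseId = caseId)
}

#' Compare complex and trimmed model metrics
#'
#' Emits paired deltas with the fixed sign convention
#' \eqn{\delta X = X_{complex} - X_{trimmed}} for the sac metrics (neck
#' inflow rate, wall-shear surrogate, OSI) and the per-path centerline
#' velocity difference curves with their maximum absolute difference.
#'
#' @param metricsComplex,metricsTrimmed [HemodynamicMetrics-class] objects
#'   computed on paired geometries (matching sac labels and path names).
#' @return A [ComparisonReport-class].
#' @export
compareModels <- function(metricsComplex, metricsTrimmed) {
  mc <- metricsComplex; mt <- metricsTrimmed
  if (!setequal(mc@sacTable$label, mt@sacTable$label))
    stop(sprintf("unpaired sac labels: %s",
                 paste(union(setdiff(mc@sacTable$label, mt@sacTable$label),
                             setdiff(mt@sacTable$label, mc@sacTable$label)),
                       collapse = ", ")))
  common <- intersect(names(mc@paths), names(mt@paths))
  if (length(common) == 0 && length(mc@paths) > 0)
    stop("no common centerline paths between the two models")
  summary <- data.frame(metric = character(0), entity = character(0),
                        complex = numeric(0), trimmed = numeric(0),
                        delta = numeric(0), stringsAsFactors = FALSE)
  addRow <- function(metric, entity, xc, xt) {
    summary <<- rbind(summary, data.frame(
      metric = metric, entity = entity, complex = xc, trimmed = xt,
      delta = xc - xt, stringsAsFactors = FALSE))
  }
  for (lab in mc@sacTable$label) {
    rc <- mc@sacTable[mc@sacTable$label == lab, ]
    rt <- mt@sacTable[mt@sacTable$label == lab, ]
    addRow("nir_mean_mls", lab, rc$nir_mean_mls, rt$nir_mean_mls)
    addRow("wss_proxy_mean_Pa", lab, rc$wss_proxy_mean_Pa, rt$wss_proxy_mean_Pa)
    addRow("wss_proxy_max_Pa", lab, rc$wss_proxy_max_Pa, rt$wss_proxy_max_Pa)
    addRow("osi", lab, rc$osi, rt$osi)
  }
  pathDiffs <- list()
  maxAbs <- 0
  for (p in common) {
    cc <- mc@paths[[p]]
    ct <- mt@paths[[p]]
    grid <- cc$arclength_mm
    vt <- approx(ct$arclength_mm, ct$velocity_m_s, xout = grid, rule = 2)$y
    df <- data.frame(arclength_mm = grid, v_complex = cc$velocity_m_s,
                     v_trimmed = vt, delta_v = cc$velocity_m_s - vt,
                     distal_to_offtake = cc$distal_to_offtake)
    pathDiffs[[p]] <- df
    maxAbs <- max(maxAbs, max(abs(df$delta_v)))
    addRow("mean_clv_m_s", p, mean(cc$velocity_m_s), mean(vt))
  }
  new("ComparisonReport", summary = summary, pathDiffs = pathDiffs,
      maxAbsPathDiff = maxAbs,
      cases = c(mc@caseId, mt@caseId))
}
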