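## Synthetic Circle-of-Willis network template.

# Fixed communicating ring: 3 inlets (ICAl, ICAr, BA), carotid termini,
# basilar top, anterior and posterior communicating junctions. Positions in
# mm; radii physiological. The ring provides the loop structure (Acom plus
# the two Pcoms) that makes the pressure solve non-trivial.
.cow_ring <- function() {
  nodes <- data.frame(
    id = c("ICAr.in", "ICAl.in", "BA.in", "ICAt.r", "ICAt.l", "BA.top",
           "AcomJ.r", "AcomJ.l", "PcomJ.r", "PcomJ.l"),
    x = c(16, -16, 0, 12, -12, 0, 2.5, -2.5, 7, -7),
    y = c(3, 3, -17, 2, 2, -11, 12, 12, -9, -9),
    z = c(-14, -14, -16, -4, -4, -5, -2, -2, -3, -3),
    kind = c("inlet", "inlet", "inlet", rep("junction", 7)),
    label = c("ICAr", "ICAl", "BA", "ICAt.r", "ICAt.l", "BA.top",
              "AcomJ.r", "AcomJ.l", "PcomJ.r", "PcomJ.l"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = c("ICA.r", "ICA.l", "BA", "A1.r", "A1.l", "Acom",
           "P1.r", "P1.l", "Pcom.r", "Pcom.l"),
    from = c("ICAr.in", "ICAl.in", "BA.in", "ICAt.r", "ICAt.l", "AcomJ.r",
             "BA.top", "BA.top", "ICAt.r", "ICAt.l"),
    to = c("ICAt.r", "ICAt.l", "BA.top", "AcomJ.r", "AcomJ.l", "AcomJ.l",
           "PcomJ.r", "PcomJ.l", "PcomJ.r", "PcomJ.l"),
    radius = c(2.0, 2.0, 1.6, 1.1, 1.1, 0.7, 1.0, 1.0, 0.7, 0.7),
    kind = "vessel",
    label = c("ICA.r", "ICA.l", "BA", "A1.r", "A1.l", "Acom",
              "P1.r", "P1.l", "Pcom.r", "Pcom.l"),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

# main trunk definitions: start junction, direction endpoint, root radius,
# and which inlet branch the trunk's outlets are book-kept under.
.cow_trunks <- function() {
  data.frame(
    name = c("MCA.r", "MCA.l", "ACA.r", "ACA.l", "PCA.r", "PCA.l"),
    start = c("ICAt.r", "ICAt.l", "AcomJ.r", "AcomJ.l", "PcomJ.r", "PcomJ.l"),
    ex = c(34, -34, 5, -5, 26, -26),
    ey = c(4, 4, 26, 26, -22, -22),
    ez = c(4, 4, 16, 16, 4, 4),
    r0 = c(1.4, 1.4, 1.1, 1.1, 1.0, 1.0),
    branch = c("ICAr", "ICAl", "ICAr", "ICAl", "BA", "BA"),
    stringsAsFactors = FALSE)
}

#' Generate a Circle-of-Willis-like vessel network template
#'
#' Builds a synthetic cerebrovascular network with exactly three inlets
#' (labelled ICAl, ICAr and BA), a communicating-artery ring (anterior
#' communicating artery plus both posterior communicating arteries, so the
#' graph always contains cycles), six main trunks (left/right MCA, ACA and
#' PCA) and a configurable total number of outlets. The first
#' \code{min(nOutlets, 6)} outlets terminate the main trunks; the remainder
#' are side branches distributed round-robin over the trunks at seeded
#' positions. Side-branch radii follow Murray's physiological branching rule
#' \eqn{r_{parent}^3 = \sum r_{child}^3}, so trunks taper distally.
#'
#' @param nOutlets total number of outlets (>= 4). The study design compares
#'   a 60-outlet complex model with a 10-outlet trimmed model.
#' @param seed integer seed; the generator is deterministic for fixed
#'   (nOutlets, seed).
#' @param minRadius lower clamp on all edge radii (mm); the default 0.7 mm
#'   keeps every branch at least ~2 voxels in radius at the default
#'   0.32 mm imaging spacing, so the imaging stage can resolve it. Use a
#'   larger clamp for coarser grids. Clamped bifurcations deviate
#'   from the exact Murray rule.
#' @param sideRadiusFactor side-branch radius as a fraction of the local
#'   trunk radius.
#' @return A [VesselNetwork-class] with labelled nodes and edges; outlet
#'   nodes carry the inlet branch they are book-kept under in
#'   \code{metadata$outletBranch}.
#' @examples
#' net <- generateCowTemplate(nOutlets = 10, seed = 1)
#' net
#' @export
generateCowTemplate <- function(nOutlets = 60, seed = 1, minRadius = 0.7,
                                sideRadiusFactor = 0.5) {
  if (!is.numeric(nOutlets) || nOutlets < 4)
    stop("nOutlets must be >= 4 (cannot place one outlet per main trunk)")
  nOutlets <- as.integer(nOutlets)
  .with_seed(seed, {
    ring <- .cow_ring()
    nodes <- ring$nodes
    edges <- ring$edges
    trunks <- .cow_trunks()
    nT <- min(nOutlets, 6L)
    trunks <- trunks[seq_len(nT), , drop = FALSE]
    nSide <- nOutlets - nT
    sides <- rep(seq_len(nT), length.out = max(nSide, 0))
    sideCount <- tabulate(sides, nbins = nT)
    outletBranch <- character(0)

    for (t in seq_len(nT)) {
      tr <- trunks[t, ]
      p0 <- as.numeric(nodes[nodes$id == tr$start, c("x", "y", "z")])
      p1 <- c(tr$ex, tr$ey, tr$ez)
      axis <- .normalize(p1 - p0)
      u <- .perp(axis)
      v <- pracma_cross(axis, u)
      m <- sideCount[t]
      fr <- if (m > 0) sort(stats::runif(m, 0.15, 0.85)) else numeric(0)
      cur <- tr$r0
      prev <- tr$start
      prevPos <- p0
      for (s in seq_len(m)) {
        jit <- 0.8 * (stats::runif(1) - 0.5) * u + 0.8 * (stats::runif(1) - 0.5) * v
        jpos <- p0 + fr[s] * (p1 - p0) + jit
        jid <- sprintf("%s.j%d", tr$name, s)
        nodes <- rbind(nodes, data.frame(
          id = jid, x = jpos[1], y = jpos[2], z = jpos[3],
          kind = "junction", label = jid, stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(
          id = sprintf("%s.%d", tr$name, s), from = prev, to = jid,
          radius = cur, kind = "vessel",
          label = tr$name, stringsAsFactors = FALSE))
        # side branch: golden-angle azimuth sequence (spreads consecutive
        # branches around the trunk so their tubes do not merge), tilted
        # slightly distally, with a small seeded wobble
        theta <- (s - 1) * 2.39996 + stats::runif(1, -0.25, 0.25)
        radial <- cos(theta) * u + sin(theta) * v
        # ACA trunks run close to the midline: keep their branches on
        # their own side
        if (grepl("^ACA", tr$name)) {
          sgn <- if (grepl("r$", tr$name)) 1 else -1
          if (sgn * radial[1] < 0.1) radial[1] <- sgn * (0.1 + abs(radial[1]))
        }
        radial <- .normalize(radial)
        dirn <- .normalize(0.35 * axis + radial)
        len <- stats::runif(1, 5, 9)
        rSide <- max(minRadius, sideRadiusFactor * cur)
        sid <- sprintf("%s.s%d", tr$name, s)
        spos <- jpos + len * dirn
        nodes <- rbind(nodes, data.frame(
          id = sid, x = spos[1], y = spos[2], z = spos[3],
          kind = "outlet", label = sid, stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(
          id = paste0(sid, ".e"), from = jid, to = sid,
          radius = rSide, kind = "vessel",
          label = sid, stringsAsFactors = FALSE))
        outletBranch[sid] <- tr$branch
        # Murray taper, floored at 75% of the trunk root: the main
        # continuation keeps its caliber dominant over side branches (whose
        # radii are inflated by the resolution clamp)
        cur <- max(minRadius, 0.75 * tr$r0,
                   (max(cur^3 - rSide^3, 1e-9))^(1 / 3))
        prev <- jid
        prevPos <- jpos
      }
      oid <- paste0(tr$name, ".out")
      nodes <- rbind(nodes, data.frame(
        id = oid, x = p1[1], y = p1[2], z = p1[3],
        kind = "outlet", label = oid, stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(
        id = paste0(oid, ".e"), from = prev, to = oid,
        radius = cur, kind = "vessel",
        label = tr$name, stringsAsFactors = FALSE))
      outletBranch[oid] <- tr$branch
    }

    pos <- as.matrix(nodes[, c("x", "y", "z")])
    rownames(pos) <- nodes$id
    edges$radius <- pmax(edges$radius, minRadius)
    edges$length <- sqrt(rowSums((pos[edges$from, , drop = FALSE] -
                                  pos[edges$to, , drop = FALSE])^2))
    nodes <- .refresh_kinds(nodes, edges)
    vesselNetwork(nodes, edges[, c("id", "from", "to", "length", "radius",
                                   "kind", "label")],
                  metadata = list(
                    generator = "generateCowTemplate",
                    nOutlets = nOutlets, seed = seed,
                    outletBranch = outletBranch,
                    inletLabels = c("ICAl", "ICAr", "BA")))
  })
}
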