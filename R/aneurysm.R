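## Parametric saccular aneurysms: specification and graph surgery.

#' Create an aneurysm specification for a network edge
#'
#' The sac is modelled as a compliant side chamber (a lumped element) joined
#' to its parent vessel by a short neck edge. The neck radius is the parent
#' edge radius scaled by \code{neckRatio}, mirroring how a patient aneurysm
#' is scaled so its parent vessel diameter matches the vessel it is grafted
#' onto.
#'
#' @param network a [VesselNetwork-class].
#' @param edgeId id of the parent edge (must be of kind "vessel").
#' @param arcPosition fractional position along the edge in [0, 1].
#' @param sacVolume sac volume (mm^3).
#' @param compliance sac compliance (m^3/Pa).
#' @param neckRatio neck radius as a fraction of the parent radius (<= 1).
#' @param neckLength effective neck length (mm).
#' @param label sac identifier, e.g. "IA-A".
#' @return An [AneurysmSpec-class].
#' @export
makeAneurysmSpec <- function(network, edgeId, arcPosition = 0.5,
                             sacVolume = 100, compliance = 1e-12,
                             neckRatio = 1.0, neckLength = 1.0,
                             label = "IA") {
  stopifnot(is(network, "VesselNetwork"))
  ed <- network@edges
  i <- match(as.character(edgeId), ed$id)
  if (is.na(i)) stop(sprintf("edge '%s' does not exist", edgeId))
  if (ed$kind[i] == "neck")
    stop("cannot place an aneurysm on a neck edge (no aneurysm on aneurysm)")
  if (neckRatio <= 0 || neckRatio > 1)
    stop("neckRatio must lie in (0, 1]: neck radius cannot exceed the parent radius")
  new("AneurysmSpec", edgeId = as.character(edgeId),
      arcPosition = arcPosition, neckRadius = neckRatio * ed$radius[i],
      neckLength = neckLength, sacVolume = sacVolume,
      compliance = compliance, label = label)
}

#' Attach an aneurysm sac to a vessel network
#'
#' Splits the target edge at the requested arc position, inserts a junction
#' node there and hangs the sac node off it through a neck edge carrying the
#' spec's neck radius and length. If the arc position falls within the snap
#' tolerance of an existing endpoint the split is snapped to that node with
#' a warning. All other edges are untouched.
#'
#' @param network a [VesselNetwork-class].
#' @param spec an [AneurysmSpec-class] created for this network.
#' @param snapTol snap tolerance (mm) for splits near existing nodes.
#' @return The augmented [VesselNetwork-class].
#' @seealso [detachAneurysm()] to undo the surgery.
#' @export
attachAneurysm <- function(network, spec, snapTol = 0.1) {
  stopifnot(is(network, "VesselNetwork"), is(spec, "AneurysmSpec"))
  validObject(spec)
  nd <- network@nodes
  ed <- network@edges
  i <- match(spec@edgeId, ed$id)
  if (is.na(i)) stop(sprintf("edge '%s' does not exist", spec@edgeId))
  if (ed$kind[i] == "neck") stop("cannot attach to a neck edge")
  from <- ed$from[i]; to <- ed$to[i]
  p0 <- as.numeric(nd[nd$id == from, c("x", "y", "z")])
  p1 <- as.numeric(nd[nd$id == to, c("x", "y", "z")])
  L <- ed$length[i]
  s <- spec@arcPosition
  sacBase <- sprintf("%s.sac", spec@label)
  nearEnd <- s * L < snapTol || (1 - s) * L < snapTol
  snapNode <- if (s * L < snapTol) from else to
  snapKind <- nd$kind[nd$id == snapNode]
  if (nearEnd && !snapKind %in% c("inlet", "outlet")) {
    warning("arc position coincides with an existing node; snapping the split")
    anchor <- snapNode
    apos <- if (s * L < snapTol) p0 else p1
    dirn <- .normalize(p1 - p0)
  } else {
    if (nearEnd) {
      ## cannot snap onto a boundary node (it must keep degree 1):
      ## nudge the split just inside the edge instead
      warning("arc position coincides with a boundary node; snapping the split just inside the edge")
      s <- if (s * L < snapTol) snapTol / L else 1 - snapTol / L
    }
    anchor <- sprintf("%s.base", sacBase)
    apos <- p0 + s * (p1 - p0)
    dirn <- .normalize(p1 - p0)
    # split the parent edge
    newEdges <- data.frame(
      id = paste0(ed$id[i], c(".a", ".b")),
      from = c(from, anchor), to = c(anchor, to),
      length = c(s * L, (1 - s) * L),
      radius = ed$radius[i], kind = "vessel",
      stringsAsFactors = FALSE)
    if (!is.null(ed$label)) newEdges$label <- ed$label[i]
    for (cn in setdiff(names(ed), names(newEdges))) newEdges[[cn]] <- ed[[cn]][i]
    newEdges <- newEdges[, names(ed), drop = FALSE]
    ed <- rbind(ed[-i, , drop = FALSE], newEdges)
    anchorRow <- data.frame(id = anchor, x = apos[1], y = apos[2], z = apos[3],
                            kind = "junction", label = anchor,
                            stringsAsFactors = FALSE)
    for (cn in setdiff(names(nd), names(anchorRow))) anchorRow[[cn]] <- NA
    nd <- rbind(nd, anchorRow[, names(nd), drop = FALSE])
  }
  off <- .perp(dirn)
  spos <- apos + spec@neckLength * off
  sacRow <- data.frame(id = sacBase, x = spos[1], y = spos[2], z = spos[3],
                       kind = "aneurysm_sac", label = spec@label,
                       stringsAsFactors = FALSE)
  for (cn in setdiff(names(nd), names(sacRow))) sacRow[[cn]] <- NA
  sacRow <- sacRow[, names(nd), drop = FALSE]
  sacRow$sac_volume_mm3 <- spec@sacVolume
  sacRow$sac_compliance_m3_per_Pa <- spec@compliance
  nd <- rbind(nd, sacRow)
  neckRow <- data.frame(id = paste0(sacBase, ".neck"), from = anchor,
                        to = sacBase, length = spec@neckLength,
                        radius = spec@neckRadius, kind = "neck",
                        stringsAsFactors = FALSE)
  for (cn in setdiff(names(ed), names(neckRow))) neckRow[[cn]] <- NA
  ed <- rbind(ed, neckRow[, names(ed), drop = FALSE])
  nd <- .refresh_kinds(nd, ed)
  vesselNetwork(nd, ed, metadata = network@metadata)
}

#' Remove an aneurysm sac, restoring the parent vessel
#'
#' Deletes the sac node and its neck edge and re-merges the split parent
#' edge, so that attach followed by detach restores a network isomorphic to
#' the input.
#'
#' @param network a [VesselNetwork-class].
#' @param label sac label to remove (all sacs if NULL).
#' @return A [VesselNetwork-class] without the sac(s).
#' @export
detachAneurysm <- function(network, label = NULL) {
  nd <- network@nodes
  ed <- network@edges
  sacs <- nd$id[nd$kind == "aneurysm_sac" &
                (is.null(label) | nd$label %in% label)]
  if (length(sacs) == 0) return(network)
  ed <- ed[!(ed$from %in% sacs | ed$to %in% sacs), , drop = FALSE]
  nd <- nd[!nd$id %in% sacs, , drop = FALSE]
  nd <- .refresh_kinds(nd, ed)
  net <- vesselNetwork(nd, ed, metadata = network@metadata)
  mergeDegreeTwo(net)
}
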