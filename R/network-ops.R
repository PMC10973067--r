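## Network operations: outlet prominence, trimming, degree-2 merging,
## branch bookkeeping.

# radius of the single edge incident to each degree-1 node
.boundary_edge_radius <- function(network, ids) {
  ed <- network@edges
  vapply(ids, function(id) {
    inc <- which(ed$from == id | ed$to == id)
    ed$radius[inc[1]]
  }, numeric(1))
}

#' Rank outlets by prominence (cross-sectional area)
#'
#' "Most prominent" is quantified as the outlet cross-sectional area
#' \eqn{\pi r^2} of the outlet's terminal edge, the attribute the study
#' design tabulates per branch; ties are broken by outlet label in
#' lexicographic order so the ranking is deterministic.
#'
#' @param network a [VesselNetwork-class] with at least one outlet.
#' @return data.frame (id, label, branch, radius_mm, area_mm2) sorted by
#'   decreasing area.
#' @export
outletProminence <- function(network) {
  out <- outletNodes(network)
  if (nrow(out) == 0) stop("network has no outlets")
  r <- .boundary_edge_radius(network, out$id)
  df <- data.frame(id = out$id, label = out$label,
                   branch = .outlet_branches(network)[out$id],
                   radius_mm = r, area_mm2 = pi * r^2,
                   stringsAsFactors = FALSE)
  df[order(-df$area_mm2, df$label), , drop = FALSE]
}

# Which inlet branch each outlet is book-kept under: from generator metadata
# when available, otherwise by weighted graph distance to the nearest inlet.
.outlet_branches <- function(network) {
  out <- outletNodes(network)$id
  meta <- network@metadata$outletBranch
  if (!is.null(meta) && all(out %in% names(meta)))
    return(setNames(unname(meta[out]), out))
  g <- .as_igraph(network)
  inl <- inletNodes(network)
  d <- igraph::distances(g, v = as.character(out),
                         to = as.character(inl$id),
                         weights = network@edges$length)
  setNames(inl$label[apply(d, 1, which.min)], out)
}

#' Trim a network to its most prominent outlets
#'
#' Removes all outlets not kept, then iteratively deletes the dangling
#' degree-1 chains they leave behind and merges the resulting degree-2
#' runs (lengths summed, radius length-weighted). Inlets are always
#' preserved; edges on paths from inlets to kept outlets keep their
#' geometry, so the trimmed and complex models share the same vasculature.
#'
#' @param network a [VesselNetwork-class].
#' @param keep either a single integer (keep the k most prominent outlets)
#'   or a character vector of outlet node ids.
#' @param merge merge degree-2 chains afterwards (default TRUE).
#' @return The trimmed [VesselNetwork-class].
#' @export
trimNetwork <- function(network, keep, merge = TRUE) {
  out <- outletNodes(network)
  if (is.numeric(keep) && length(keep) == 1) {
    if (keep < 1 || keep > nrow(out))
      stop("keep must be between 1 and the number of outlets")
    keepIds <- head(outletProminence(network)$id, keep)
  } else {
    keepIds <- as.character(keep)
    if (!all(keepIds %in% out$id)) stop("unknown outlet id in keep")
  }
  nd <- network@nodes
  ed <- network@edges
  drop <- setdiff(out$id, keepIds)
  nd <- nd[!nd$id %in% drop, , drop = FALSE]
  ed <- ed[!(ed$from %in% drop | ed$to %in% drop), , drop = FALSE]
  # iteratively delete dangling degree-1 nodes that are not boundary nodes
  repeat {
    deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
    dangling <- nd$id[deg == 1 & !nd$kind %in% c("inlet", "outlet", "aneurysm_sac")]
    orphans <- nd$id[deg == 0]
    if (length(dangling) == 0 && length(orphans) == 0) break
    nd <- nd[!nd$id %in% c(dangling, orphans), , drop = FALSE]
    ed <- ed[!(ed$from %in% dangling | ed$to %in% dangling), , drop = FALSE]
  }
  deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
  if (any(deg[nd$kind == "inlet"] != 1))
    stop("trimming would disconnect an inlet")
  nd <- .refresh_kinds(nd, ed)
  meta <- network@metadata
  if (!is.null(meta$outletBranch))
    meta$outletBranch <- meta$outletBranch[names(meta$outletBranch) %in% keepIds]
  net <- vesselNetwork(nd, ed, metadata = meta)
  if (merge) mergeDegreeTwo(net) else net
}

#' Merge degree-2 chains into single edges
#'
#' Consecutive vessel edges meeting at an internal degree-2 node are fused:
#' lengths are summed and the radius is the length-weighted mean, which
#' preserves total Poiseuille resistance better than an arithmetic mean for
#' mild taper. Boundary nodes, sacs and neck attachments are never merged,
#' and merges that would collapse a loop into a self-edge are skipped.
#'
#' @param network a [VesselNetwork-class].
#' @return A [VesselNetwork-class] with maximal chains merged.
#' @export
mergeDegreeTwo <- function(network) {
  nd <- network@nodes
  ed <- network@edges
  repeat {
    deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
    cand <- nd$id[deg == 2 & nd$kind %in% c("internal", "junction")]
    merged <- FALSE
    for (v in cand) {
      inc <- which(ed$from == v | ed$to == v)
      if (length(inc) != 2) next
      if (any(ed$kind[inc] != "vessel")) next
      e1 <- inc[1]; e2 <- inc[2]
      a <- if (ed$from[e1] == v) ed$to[e1] else ed$from[e1]
      b <- if (ed$from[e2] == v) ed$to[e2] else ed$from[e2]
      if (a == b) next  # would create a self-loop
      l1 <- ed$length[e1]; l2 <- ed$length[e2]
      newRow <- ed[e1, , drop = FALSE]
      newRow$from <- a; newRow$to <- b
      newRow$length <- l1 + l2
      newRow$radius <- (l1 * ed$radius[e1] + l2 * ed$radius[e2]) / (l1 + l2)
      ed <- rbind(ed[-inc, , drop = FALSE], newRow)
      nd <- nd[nd$id != v, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  nd <- .refresh_kinds(nd, ed)
  vesselNetwork(nd, ed, metadata = network@metadata)
}

#' Per-branch outlet summary for a complex/trimmed model pair
#'
#' Mirrors the study's model-parameter bookkeeping: for each inlet branch,
#' the number of outlets and the summed outlet cross-sectional area in the
#' trimmed and the complex model.
#'
#' @param complex,trimmed [VesselNetwork-class] objects.
#' @return data.frame (branch, n_outlets_trimmed, n_outlets_complex,
#'   sum_area_trimmed_mm2, sum_area_complex_mm2).
#' @export
branchSummary <- function(complex, trimmed) {
  pc <- outletProminence(complex)
  pt <- outletProminence(trimmed)
  branches <- sort(unique(c(pc$branch, pt$branch)))
  data.frame(
    branch = branches,
    n_outlets_trimmed = vapply(branches, function(b) sum(pt$branch == b), 0L),
    n_outlets_complex = vapply(branches, function(b) sum(pc$branch == b), 0L),
    sum_area_trimmed_mm2 = vapply(branches, function(b)
      sum(pt$area_mm2[pt$branch == b]), 0),
    sum_area_complex_mm2 = vapply(branches, function(b)
      sum(pc$area_mm2[pc$branch == b]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Find the network edge nearest to a world point
#'
#' @param network a [VesselNetwork-class].
#' @param point numeric(3) world position (mm).
#' @param kinds edge kinds to consider.
#' @return list(id, distance_mm, arcPosition) of the closest edge.
#' @export
nearestEdge <- function(network, point, kinds = "vessel") {
  ed <- network@edges
  segs <- .edge_segments(network)
  best <- NULL
  for (i in seq_len(nrow(ed))) {
    if (!ed$kind[i] %in% kinds) next
    a <- segs[i, 1:3]; b <- segs[i, 4:6]
    u <- b - a
    tt <- sum((point - a) * u) / max(sum(u * u), 1e-12)
    tt <- min(max(tt, 0), 1)
    d <- sqrt(sum((point - (a + tt * u))^2))
    if (is.null(best) || d < best$distance_mm)
      best <- list(id = ed$id[i], distance_mm = d, arcPosition = tt)
  }
  best
}
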