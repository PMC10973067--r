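## Centerline extraction: 3D thinning to a curve skeleton, then conversion
## to a vessel graph with per-edge radius from the distance transform.

#' Euclidean distance transform of a mask (voxel units)
#'
#' Distance from each foreground voxel center to the nearest background
#' voxel center.
#'
#' @param mask a [SegmentationMask-class], GroundTruth, or logical array.
#' @return numeric array of distances in voxels.
#' @export
distanceTransform <- function(mask) {
  m <- if (is.array(mask)) mask else voxelData(mask)
  d <- dim(m)
  out <- sqrt(.sq_edt(m, d))
  dim(out) <- d
  out
}

#' Build a vessel network from a segmentation mask
#'
#' Thins the mask to a one-voxel curve skeleton (topology-preserving
#' deletion of simple points by directional sub-iterations, curve endpoints
#' preserved), converts it to a graph (skeleton voxels of
#' degree != 2 become nodes, chains become edges), measures each edge's
#' length as its polyline arc length and its radius as the mean corrected
#' distance-transform value along the chain, prunes thinning spurs shorter
#' than twice the local radius, merges degree-2 runs and finally binds
#' opening metadata (inlet/outlet labels) to degree-1 nodes by proximity.
#'
#' The default radius correction has two parts, both in voxels: a quarter
#' voxel for the offset between the nearest background voxel center and the
#' actual mask surface (the expectation over sub-voxel boundary positions),
#' plus \code{boundaryLevel - 0.5} to undo the sub-voxel bias of a mask
#' whose boundary sits above the half-maximum level -- a relative-band
#' region growing with tolerance 0.02 places the boundary at the 98\%
#' intensity level, about 0.48 voxel inside the half-maximum lumen surface
#' on a one-voxel partial-volume edge.
#'
#' @param mask a [SegmentationMask-class] (connected; clean first).
#' @param openings optional data.frame (label, kind, x, y, z, radius) of
#'   known end positions (mm) to bind to degree-1 nodes.
#' @param pruneSpurs remove short terminal spurs (default TRUE).
#' @param radiusCorrection added to the distance transform (voxels); NULL
#'   selects 0.25 + (boundaryLevel - 0.5) as described above.
#' @param maxOpeningDist maximum match distance (mm) between an opening and
#'   a degree-1 node; default 4 mm + 2 x opening radius.
#' @return A [VesselNetwork-class].
#' @export
skeletonizeNetwork <- function(mask, openings = NULL, pruneSpurs = TRUE,
                               radiusCorrection = NULL,
                               maxOpeningDist = NULL) {
  if (is.null(radiusCorrection)) {
    lvl <- if (is(mask, "SegmentationMask")) mask@boundaryLevel else 0.5
    radiusCorrection <- 0.25 + (lvl - 0.5)
  }
  m <- voxelData(mask)
  d <- dim(m)
  spacing <- voxelSpacing(mask)
  origin <- voxelOrigin(mask)
  edt <- sqrt(.sq_edt(m, d))
  skel <- .skeletonize3d(m, d)
  dim(skel) <- d
  lin <- which(skel)
  if (length(lin) == 0) stop("empty skeleton")
  coords <- arr.ind_fast(lin, d)
  id <- integer(prod(d))
  id[lin] <- seq_along(lin)

  ## 26-neighborhood adjacency among skeleton voxels
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[with(offs, di + 3 * dj + 9 * dk) > 0, ]  # half the offsets
  pairs <- NULL
  for (o in seq_len(nrow(offs))) {
    ni <- coords[, 1] + offs$di[o]
    nj <- coords[, 2] + offs$dj[o]
    nk <- coords[, 3] + offs$dk[o]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nl <- ni[ok] + (nj[ok] - 1) * d[1] + (nk[ok] - 1) * d[1] * d[2]
    nid <- id[nl]
    hit <- nid > 0
    pairs <- rbind(pairs, cbind(which(ok)[hit], nid[hit]))
  }
  nV <- length(lin)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nV - igraph::vcount(g)))
  deg <- igraph::degree(g)

  isNode <- deg != 2
  if (!any(isNode)) isNode[1] <- TRUE  # a pure cycle: anchor one node

  ## cluster adjacent node voxels into single junction nodes
  nodeIdx <- which(isNode)
  sub <- igraph::induced_subgraph(g, nodeIdx)
  cl <- igraph::components(sub)$membership
  cluster <- integer(nV)
  cluster[nodeIdx] <- cl
  nClust <- max(cl)
  world <- sweep((coords - 1) * spacing, 2, origin, "+")
  cpos <- t(vapply(seq_len(nClust), function(k) {
    v <- nodeIdx[cl == k]
    # anchor each cluster at its most interior voxel
    v[which.max(edt[lin[v]])]
    colMeans(world[v, , drop = FALSE])
  }, numeric(3)))
  crad <- vapply(seq_len(nClust), function(k) {
    v <- nodeIdx[cl == k]
    mean(edt[lin[v]] + radiusCorrection) * spacing
  }, numeric(1))

  adjlist <- igraph::as_adj_list(g)
  edgesOut <- list()
  addEdge <- function(c1, c2, pathIdx) {
    pts <- rbind(cpos[c1, ], world[pathIdx, , drop = FALSE], cpos[c2, ])
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    rad <- if (length(pathIdx) > 0)
      mean(edt[lin[pathIdx]] + radiusCorrection) * spacing
    else mean(crad[c(c1, c2)])
    edgesOut[[length(edgesOut) + 1]] <<- list(from = c1, to = c2,
                                              length = max(len, 1e-6),
                                              radius = max(rad, 0.25 * spacing))
  }

  ## chains: components of the degree-2 subgraph
  chainIdx <- which(!isNode)
  if (length(chainIdx) > 0) {
    subc <- igraph::induced_subgraph(g, chainIdx)
    ccl <- igraph::components(subc)$membership
    for (k in seq_len(max(ccl))) {
      members <- chainIdx[ccl == k]
      subg <- igraph::induced_subgraph(g, members)
      dsub <- igraph::degree(subg)
      ends <- members[dsub < 2]
      if (length(ends) == 0) next  # floating cycle of degree-2 voxels
      if (length(members) == 1) {
        ordered <- members
      } else {
        pth <- igraph::shortest_paths(subg, from = which(members == ends[1]),
                                      to = which(members == ends[length(ends)]))
        ordered <- members[as.integer(pth$vpath[[1]])]
      }
      endClusters <- lapply(c(ordered[1], ordered[length(ordered)]), function(v)
        unique(cluster[intersect(adjlist[[v]], nodeIdx)]))
      c1 <- endClusters[[1]]; c2 <- endClusters[[2]]
      if (length(c1) == 0 || length(c2) == 0) next
      c1 <- c1[1]; c2 <- c2[length(c2)]
      if (c1 == c2 && length(ordered) >= 2) {
        ## loop returning to one junction: split at the chain midpoint
        mid <- ceiling(length(ordered) / 2)
        nClust <- nClust + 1
        cpos <- rbind(cpos, world[ordered[mid], ])
        crad <- c(crad, (edt[lin[ordered[mid]]] + radiusCorrection) * spacing)
        addEdge(c1, nClust, head(ordered, mid - 1))
        addEdge(nClust, c2, tail(ordered, length(ordered) - mid))
      } else {
        addEdge(c1, c2, ordered)
      }
    }
  }
  ## direct adjacency between different clusters
  nodePairs <- pairs[isNode[pairs[, 1]] & isNode[pairs[, 2]], , drop = FALSE]
  if (nrow(nodePairs) > 0) {
    cp <- cbind(cluster[nodePairs[, 1]], cluster[nodePairs[, 2]])
    cp <- unique(t(apply(cp[cp[, 1] != cp[, 2], , drop = FALSE], 1, sort)))
    if (length(cp) > 0)
      for (rI in seq_len(nrow(cp))) addEdge(cp[rI, 1], cp[rI, 2], integer(0))
  }
  if (length(edgesOut) == 0) stop("skeleton yielded no edges")

  nodes <- data.frame(id = sprintf("n%03d", seq_len(nClust)),
                      x = cpos[, 1], y = cpos[, 2], z = cpos[, 3],
                      kind = "internal", label = sprintf("n%03d", seq_len(nClust)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(
    id = sprintf("e%03d", seq_along(edgesOut)),
    from = nodes$id[vapply(edgesOut, `[[`, 0, "from")],
    to = nodes$id[vapply(edgesOut, `[[`, 0, "to")],
    length = vapply(edgesOut, `[[`, 0, "length"),
    radius = vapply(edgesOut, `[[`, 0, "radius"),
    kind = "vessel", stringsAsFactors = FALSE)
  ## drop nodes that received no edges
  used <- unique(c(edges$from, edges$to))
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  nodes <- .refresh_kinds(nodes, edges)
  ## temporarily declare degree-1 tips as outlets so validity holds
  deg2 <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$kind[deg2 == 1] <- "outlet"
  net <- vesselNetwork(nodes, edges,
                       metadata = list(source = "skeletonizeNetwork"))
  if (pruneSpurs) net <- .prune_spurs(net)
  net <- mergeDegreeTwo(net)
  if (!is.null(openings)) net <- .bind_openings(net, openings, maxOpeningDist)
  net
}

# remove terminal chains shorter than 2 x their radius (thinning artifacts)
.prune_spurs <- function(net) {
  repeat {
    nd <- net@nodes
    ed <- net@edges
    deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
    tips <- nd$id[deg == 1]
    spur <- vapply(seq_len(nrow(ed)), function(i) {
      tipEnd <- (ed$from[i] %in% tips) + (ed$to[i] %in% tips)
      tipEnd >= 1 && ed$length[i] < 2 * ed$radius[i]
    }, logical(1))
    ## never delete the last edges; keep at least a connected core
    if (!any(spur) || sum(!spur) == 0) break
    ed <- ed[!spur, , drop = FALSE]
    keep <- unique(c(ed$from, ed$to))
    nd <- nd[nd$id %in% keep, , drop = FALSE]
    nd <- .refresh_kinds(nd, ed)
    deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
    nd$kind[deg == 1] <- "outlet"
    net <- mergeDegreeTwo(vesselNetwork(nd, ed, metadata = net@metadata))
  }
  net
}

.bind_openings <- function(net, openings, maxOpeningDist = NULL) {
  nd <- net@nodes
  ed <- net@edges
  deg <- table(factor(c(ed$from, ed$to), levels = nd$id))
  tips <- which(deg == 1)
  tipPos <- as.matrix(nd[tips, c("x", "y", "z")])
  ## globally greedy assignment: repeatedly bind the closest
  ## (opening, free tip) pair, so a nearby opening cannot steal another's tip
  D <- matrix(Inf, nrow(openings), length(tips))
  for (o in seq_len(nrow(openings))) {
    p <- as.numeric(openings[o, c("x", "y", "z")])
    D[o, ] <- sqrt(rowSums(sweep(tipPos, 2, p)^2))
  }
  rad <- if ("radius" %in% names(openings)) openings$radius else rep(1, nrow(openings))
  lim <- if (is.null(maxOpeningDist)) 4 + 2 * rad else rep(maxOpeningDist, nrow(openings))
  for (it in seq_len(nrow(openings))) {
    j <- arrayInd(which.min(D), dim(D))
    o <- j[1]; tp <- j[2]
    if (!is.finite(D[o, tp]) || D[o, tp] > lim[o])
      stop(sprintf("skeleton disconnected from opening '%s' (nearest free tip %.2f mm away)",
                   openings$label[o], D[o, tp]))
    nd$kind[tips[tp]] <- as.character(openings$kind[o])
    nd$label[tips[tp]] <- as.character(openings$label[o])
    D[o, ] <- Inf
    D[, tp] <- Inf
  }
  vesselNetwork(nd, ed, metadata = net@metadata)
}

#' End positions and normals of a network's boundary nodes
#'
#' Convenience helper: extracts (label, kind, position, outward normal,
#' radius) for every inlet and outlet of a network, e.g. to drive
#' [cutAndExtrudeEnds()] or to bind labels to a recovered skeleton.
#'
#' @param network a [VesselNetwork-class].
#' @return data.frame (label, kind, x, y, z, nx, ny, nz, radius).
#' @export
openingsFromNetwork <- function(network) {
  nd <- network@nodes
  ed <- network@edges
  b <- nd[nd$kind %in% c("inlet", "outlet"), , drop = FALSE]
  pos <- as.matrix(nd[, c("x", "y", "z")])
  rownames(pos) <- nd$id
  res <- lapply(seq_len(nrow(b)), function(i) {
    id <- b$id[i]
    inc <- which(ed$from == id | ed$to == id)[1]
    other <- if (ed$from[inc] == id) ed$to[inc] else ed$from[inc]
    n <- .normalize(pos[id, ] - pos[other, ])
    data.frame(label = b$label[i], kind = b$kind[i],
               x = pos[id, 1], y = pos[id, 2], z = pos[id, 3],
               nx = n[1], ny = n[2], nz = n[3],
               radius = ed$radius[inc], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# fast replacement for arrayInd on 3D grids
arr.ind_fast <- function(lin, d) {
  i <- ((lin - 1) %% d[1]) + 1
  j <- (((lin - 1) %/% d[1]) %% d[2]) + 1
  k <- ((lin - 1) %/% (d[1] * d[2])) + 1
  cbind(i, j, k)
}
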