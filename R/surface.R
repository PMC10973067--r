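## Surface extraction and mesh operations.

#' Extract a closed triangulated surface from a segmentation mask
#'
#' The binary mask is converted to a smooth indicator (Gaussian smoothing,
#' default sigma 0.5 voxel, reducing voxel stair-stepping) and triangulated
#' at the given iso-level by marching cubes in its tetrahedral-decomposition
#' variant, which guarantees a watertight surface. Vertices are in world
#' millimetres (voxel-center convention).
#'
#' @param mask a [SegmentationMask-class] (or GroundTruth) whose foreground
#'   must not touch the grid boundary. An [ImageVolume-class] may be given
#'   instead for grey-level isosurfacing (e.g. of the partial-volume
#'   fraction field, which carries sub-voxel boundary information); the
#'   iso-level is then in intensity units and smoothing defaults to off.
#' @param isoLevel iso-level on the smoothed indicator, default 0.5.
#' @param smoothSigma indicator smoothing in voxels (0 = raw indicator).
#' @return A closed [SurfaceMesh-class].
#' @export
extractSurface <- function(mask, isoLevel = 0.5,
                           smoothSigma = if (is(mask, "ImageVolume")) 0 else 0.5) {
  grey <- is(mask, "ImageVolume")
  m <- voxelData(mask)
  d <- dim(m)
  fg <- if (grey) m > isoLevel else m
  if (!any(fg)) stop("mask has no foreground voxel")
  idx <- which(fg, arr.ind = TRUE)
  if (any(idx == 1) || any(sweep(idx, 2, d) == 0))
    stop("foreground touches the grid boundary; pad the mask first")
  field <- as.numeric(m)
  if (smoothSigma > 0) field <- .gauss_smooth(field, d, smoothSigma)
  if (max(field) <= isoLevel)
    stop("no isosurface at this level (smoothing may have flattened a tiny mask; lower smoothSigma)")
  res <- .march_tets(field, d, isoLevel, voxelSpacing(mask),
                     voxelOrigin(mask) - voxelSpacing(mask))
  ## origin shift: .march_tets uses 0-based indices, R grids are 1-based
  mesh <- new("SurfaceMesh", vertices = res$vertices,
              triangles = res$triangles,
              openings = .empty_openings())
  dropDegenerateTriangles(mesh)
}

.empty_openings <- function() {
  data.frame(id = character(0), label = character(0), kind = character(0),
             cx = numeric(0), cy = numeric(0), cz = numeric(0),
             nx = numeric(0), ny = numeric(0), nz = numeric(0),
             area_mm2 = numeric(0), stringsAsFactors = FALSE)
}

#' Remove zero-area triangles
#'
#' @param mesh a [SurfaceMesh-class].
#' @param tol area threshold (mm^2) below which a triangle counts as
#'   degenerate.
#' @return A [SurfaceMesh-class].
#' @export
dropDegenerateTriangles <- function(mesh, tol = 1e-12) {
  a <- .triangle_areas(mesh)
  keep <- a > tol
  new("SurfaceMesh", vertices = mesh@vertices,
      triangles = mesh@triangles[keep, , drop = FALSE],
      openings = mesh@openings)
}

.triangle_areas <- function(mesh) {
  V <- mesh@vertices
  Tm <- mesh@triangles
  u <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  w <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh surface area (mm^2)
#' @param mesh a [SurfaceMesh-class].
#' @export
meshArea <- function(mesh) sum(.triangle_areas(mesh))

#' Enclosed volume (mm^3) of a closed mesh (divergence theorem)
#' @param mesh a [SurfaceMesh-class].
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices
  Tm <- mesh@triangles
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE]
  cc <- V[Tm[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
         a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
         a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det)) / 6
}

# undirected edge table: one row per triangle edge occurrence
.mesh_edge_df <- function(mesh) {
  Tm <- mesh@triangles
  e <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  data.frame(a = pmin(e[, 1], e[, 2]), b = pmax(e[, 1], e[, 2]))
}

#' Is every mesh edge shared by exactly two triangles?
#' @param mesh a [SurfaceMesh-class].
#' @export
meshIsClosed <- function(mesh) {
  ed <- .mesh_edge_df(mesh)
  cnt <- table(paste(ed$a, ed$b))
  all(cnt == 2)
}

#' Boundary loops of an open mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list of integer vectors, each an ordered cycle of vertex indices
#'   along one boundary loop.
#' @export
meshBoundaryLoops <- function(mesh) {
  ed <- .mesh_edge_df(mesh)
  key <- paste(ed$a, ed$b)
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]
  if (length(bkey) == 0) return(list())
  bed <- unique(ed[key %in% bkey, , drop = FALSE])
  adj <- split(c(bed$b, bed$a), c(bed$a, bed$b))
  visited <- character(0)
  loops <- list()
  for (start in as.integer(names(adj))) {
    if (as.character(start) %in% visited) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- start
    repeat {
      loop <- c(loop, cur)
      visited <- c(visited, as.character(cur))
      nxt <- setdiff(adj[[as.character(cur)]], c(prev))
      nxt <- nxt[!(as.character(nxt) %in% visited)]
      if (length(nxt) == 0) break
      prev <- cur
      cur <- nxt[1]
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Laplacian mesh smoothing
#'
#' Each iteration moves every vertex toward the centroid of its 1-ring
#' neighbors by the given step (uniform umbrella weights); connectivity is
#' unchanged and iterations = 0 is the identity.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param iterations number of smoothing sweeps (default 20).
#' @param step relaxation factor in (0, 1] (default 0.5).
#' @return The smoothed [SurfaceMesh-class].
#' @export
smoothSurface <- function(mesh, iterations = 20, step = 0.5) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (step <= 0 || step > 1) stop("step must lie in (0, 1]")
  if (iterations == 0) return(mesh)
  ed <- unique(.mesh_edge_df(mesh))
  n <- nrow(mesh@vertices)
  A <- Matrix::sparseMatrix(i = c(ed$a, ed$b), j = c(ed$b, ed$a),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- mesh@vertices
  for (it in seq_len(iterations)) {
    V <- (1 - step) * V + step * as.matrix(A %*% V) / deg
  }
  new("SurfaceMesh", vertices = V, triangles = mesh@triangles,
      openings = mesh@openings)
}

# keep the connected component with the largest surface area
.mesh_largest_component <- function(mesh) {
  ed <- unique(.mesh_edge_df(mesh))
  n <- nrow(mesh@vertices)
  g <- igraph::graph_from_edgelist(as.matrix(ed), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  triComp <- comp[mesh@triangles[, 1]]
  areas <- .triangle_areas(mesh)
  byComp <- tapply(areas, triComp, sum)
  keepComp <- as.integer(names(byComp)[which.max(byComp)])
  keepTri <- triComp == keepComp
  Tm <- mesh@triangles[keepTri, , drop = FALSE]
  used <- sort(unique(as.vector(Tm)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  new("SurfaceMesh", vertices = mesh@vertices[used, , drop = FALSE],
      triangles = matrix(remap[Tm], ncol = 3),
      openings = mesh@openings)
}

#' Cut mesh ends perpendicular to the centerline and extrude them
#'
#' For each end, the mesh is sliced by the plane through the end point with
#' the given outward normal (the local centerline tangent); the distal cap
#' is removed, the cut rim is closed into a planar loop, and a straight
#' prismatic extension of the requested length is appended, ending in an
#' open boundary loop. The per-opening planar cross-section area, centroid
#' and normal are recorded in the returned mesh's openings table.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param ends data.frame with columns label, kind ("inlet"/"outlet"),
#'   x, y, z (end point, mm), nx, ny, nz (outward unit normal) and radius
#'   (local vessel radius, mm; used to localize the cut).
#' @param extrusionLength length of the prismatic extension (mm); 0 leaves
#'   the bare cut loop open.
#' @return An open [SurfaceMesh-class] with one boundary loop per end.
#' @export
cutAndExtrudeEnds <- function(mesh, ends, extrusionLength = 4) {
  stopifnot(is(mesh, "SurfaceMesh"))
  V <- mesh@vertices
  Tm <- mesh@triangles
  openings <- .empty_openings()
  for (e in seq_len(nrow(ends))) {
    p <- as.numeric(ends[e, c("x", "y", "z")])
    d <- .normalize(as.numeric(ends[e, c("nx", "ny", "nz")]))
    r <- if ("radius" %in% names(ends)) ends$radius[e] else NA
    s <- as.vector((V - matrix(p, nrow(V), 3, byrow = TRUE)) %*% d)
    q <- V - matrix(p, nrow(V), 3, byrow = TRUE)
    ax <- q - outer(s, d)
    axdist <- sqrt(rowSums(ax^2))
    rloc <- if (is.finite(r)) 2.5 * r else stats::quantile(axdist[s > 0], 0.25)
    start <- which(s > 0 & axdist < rloc)
    if (length(start) == 0)
      stop(sprintf("slicing plane misses the mesh for end '%s'", ends$label[e]))
    ## flood the distal cap: vertices with s > 0 reachable from the start set
    ced <- unique(.mesh_edge_df(new("SurfaceMesh", vertices = V,
                                    triangles = Tm,
                                    openings = .empty_openings())))
    pos <- s > 0
    keepEdge <- pos[ced$a] & pos[ced$b]
    g <- igraph::graph_from_edgelist(as.matrix(ced[keepEdge, , drop = FALSE]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(V) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    capComp <- unique(comp[start])
    inCap <- pos & comp %in% capComp
    nDrop <- inCap[Tm[, 1]] + inCap[Tm[, 2]] + inCap[Tm[, 3]]
    if (!any(nDrop > 0 & nDrop < 3))
      stop(sprintf("slicing plane misses the mesh for end '%s'", ends$label[e]))
    keepTri <- Tm[nDrop == 0, , drop = FALSE]
    mixed <- Tm[nDrop > 0 & nDrop < 3, , drop = FALSE]
    ## clip mixed triangles against the plane s = 0 (Sutherland-Hodgman),
    ## sharing cut vertices across triangles through an edge-key map
    newV <- list()
    cutIndex <- new.env(parent = emptyenv())
    newTri <- list()
    nV <- nrow(V)
    getCut <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- get0(key, envir = cutIndex)
      if (!is.null(hit)) return(hit)
      t <- s[a] / (s[a] - s[b])
      ## snap near-endpoint intersections to the existing vertex so the
      ## plane may pass exactly through mesh vertices without duplicating
      ## them
      if (t < 1e-6) { assign(key, a, envir = cutIndex); return(a) }
      if (t > 1 - 1e-6) { assign(key, b, envir = cutIndex); return(b) }
      pnt <- V[a, ] + t * (V[b, ] - V[a, ])
      id <- nV + length(newV) + 1
      newV[[length(newV) + 1]] <<- pnt
      assign(key, id, envir = cutIndex)
      id
    }
    for (ti in seq_len(nrow(mixed))) {
      tri <- mixed[ti, ]
      poly <- integer(0)
      for (k in 1:3) {
        a <- tri[k]
        b <- tri[if (k == 3) 1 else k + 1]
        if (!inCap[a]) poly <- c(poly, a)
        if (inCap[a] != inCap[b]) poly <- c(poly, getCut(a, b))
      }
      ## drop consecutive duplicates produced by snapped intersections
      if (length(poly) > 1)
        poly <- poly[poly != c(poly[-1], poly[1])]
      if (length(poly) >= 3)
        for (k in 2:(length(poly) - 1))
          newTri[[length(newTri) + 1]] <- c(poly[1], poly[k], poly[k + 1])
    }
    if (length(newV) > 0) V <- rbind(V, do.call(rbind, newV))
    Tm <- rbind(keepTri, do.call(rbind, newTri))
    ## order the rim into a loop: of all boundary loops, take the one whose
    ## vertices lie closest to the cut plane
    tmpMesh <- new("SurfaceMesh", vertices = V, triangles = Tm,
                   openings = .empty_openings())
    loops <- meshBoundaryLoops(tmpMesh)
    if (length(loops) == 0)
      stop(sprintf("cutting end '%s' produced no boundary loop", ends$label[e]))
    planeDist <- vapply(loops, function(l)
      mean(abs(as.vector((V[l, , drop = FALSE] -
                          matrix(p, length(l), 3, byrow = TRUE)) %*% d))),
      numeric(1))
    loop <- loops[[which.min(planeDist)]]
    centroid <- colMeans(V[loop, , drop = FALSE])
    qi <- sweep(V[loop, , drop = FALSE], 2, centroid)
    nl <- length(loop)
    nxt <- c(2:nl, 1)
    crossSum <- colSums(cbind(
      qi[, 2] * qi[nxt, 3] - qi[, 3] * qi[nxt, 2],
      qi[, 3] * qi[nxt, 1] - qi[, 1] * qi[nxt, 3],
      qi[, 1] * qi[nxt, 2] - qi[, 2] * qi[nxt, 1]))
    area <- abs(0.5 * sum(crossSum * d))
    if (extrusionLength > 0) {
      ext <- V[loop, , drop = FALSE] +
        matrix(d * extrusionLength, nl, 3, byrow = TRUE)
      extIdx <- nrow(V) + seq_len(nl)
      V <- rbind(V, ext)
      ## orient side quads consistently with the loop winding
      flip <- sum(crossSum * d) < 0
      for (k in seq_len(nl)) {
        a <- loop[k]; b <- loop[nxt[k]]
        a2 <- extIdx[k]; b2 <- extIdx[nxt[k]]
        if (flip) {
          Tm <- rbind(Tm, c(a, b, b2), c(a, b2, a2))
        } else {
          Tm <- rbind(Tm, c(b, a, a2), c(b, a2, b2))
        }
      }
      centroid <- centroid + d * extrusionLength
    }
    openings <- rbind(openings, data.frame(
      id = sprintf("open%02d", e),
      label = as.character(ends$label[e]),
      kind = if ("kind" %in% names(ends)) as.character(ends$kind[e]) else "outlet",
      cx = centroid[1], cy = centroid[2], cz = centroid[3],
      nx = d[1], ny = d[2], nz = d[3],
      area_mm2 = area, stringsAsFactors = FALSE))
  }
  out <- new("SurfaceMesh", vertices = V, triangles = Tm, openings = openings)
  out <- dropDegenerateTriangles(out)
  ## drop vertices orphaned by cap removal
  used <- sort(unique(as.vector(out@triangles)))
  remap <- integer(nrow(out@vertices))
  remap[used] <- seq_along(used)
  new("SurfaceMesh", vertices = out@vertices[used, , drop = FALSE],
      triangles = matrix(remap[out@triangles], ncol = 3),
      openings = out@openings)
}
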