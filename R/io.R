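## Standard-format I/O: network JSON/GraphML, waveform CSV, NIfTI volumes,
## STL/PLY meshes, simulation and metrics tables.

#' Write / read a vessel network as JSON
#'
#' Documented schema: an object with \code{format}, \code{version},
#' \code{units}, \code{nodes} (id, x, y, z, kind, label, sac attributes),
#' \code{edges} (id, from, to, length, radius, kind) and \code{metadata}.
#' The round trip is lossless.
#'
#' @param network a [VesselNetwork-class].
#' @param path output file.
#' @return \code{writeNetworkJSON} returns the path invisibly;
#'   \code{readNetworkJSON} returns a [VesselNetwork-class].
#' @export
writeNetworkJSON <- function(network, path) {
  meta <- network@metadata
  units <- meta$units
  meta$units <- NULL
  if (!is.null(meta$outletBranch))
    meta$outletBranch <- as.list(meta$outletBranch)
  nodes <- network@nodes
  edges <- network@edges
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  obj <- list(format = "cowflow-network", version = 1L,
              units = units, nodes = nodes, edges = edges,
              metadata = meta)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cowflow-network"))
    stop("not a cowflow network JSON file")
  meta <- as.list(obj$metadata)
  if (!is.null(meta$outletBranch)) meta$outletBranch <- unlist(meta$outletBranch)
  meta$units <- obj$units
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  vesselNetwork(nodes, edges, metadata = meta)
}

#' Export a vessel network as GraphML
#'
#' @param network a [VesselNetwork-class].
#' @param path output file.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- .as_igraph(network)
  nd <- network@nodes
  ord <- match(igraph::V(g)$name, nd$id)
  for (cn in c("x", "y", "z", "kind", "label"))
    g <- igraph::set_vertex_attr(g, cn, value = nd[[cn]][ord])
  ed <- network@edges
  for (cn in c("length", "radius", "kind"))
    g <- igraph::set_edge_attr(g, cn, value = ed[[cn]])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read an image volume as NIfTI
#'
#' @param volume an [ImageVolume-class] (or SegmentationMask / GroundTruth,
#'   written as 0/1).
#' @param path a .nii or .nii.gz file.
#' @export
writeVolumeNIfTI <- function(volume, path) {
  arr <- voxelData(volume)
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  sp <- voxelSpacing(volume)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, sp, sp)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  imageVolume(array(as.numeric(img), dim = dim(img)), spacing = sp)
}

#' Write / read an inlet waveform as two-column CSV (time_s, flow_l_per_s)
#'
#' @param waveform a [FlowWaveform-class].
#' @param path output file.
#' @export
writeWaveformCSV <- function(waveform, path) {
  df <- data.frame(time_s = waveformTime(waveform),
                   flow_l_per_s = waveformFlow(waveform))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWaveformCSV
#' @param label inlet label to attach on read.
#' @export
readWaveformCSV <- function(path, label = "") {
  df <- read.csv(path)
  new("FlowWaveform", period = max(df$time_s), flow = df$flow_l_per_s,
      label = label)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output .stl file.
#' @export
writeSTL <- function(mesh, path) {
  V <- mesh@vertices
  Tm <- mesh@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cowflow", con)
  for (i in seq_len(nrow(Tm))) {
    a <- V[Tm[i, 1], ]; b <- V[Tm[i, 2], ]; cc <- V[Tm[i, 3], ]
    n <- pracma_cross(b - a, cc - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
      sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
      sprintf("      vertex %g %g %g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid cowflow", con)
  invisible(path)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output .ply file.
#' @export
writePLY <- function(mesh, path) {
  V <- mesh@vertices
  Tm <- mesh@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(Tm)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", Tm[, 1] - 1, Tm[, 2] - 1, Tm[, 3] - 1), con)
  invisible(path)
}

#' Write a simulation result as long-format CSV
#'
#' Columns: time_s, edge_id, Q_m3s, tau_Pa.
#'
#' @param result a [SimulationResult-class].
#' @param path output file.
#' @export
writeSimulationCSV <- function(result, path) {
  nE <- nrow(result@flows)
  nT <- length(result@time)
  df <- data.frame(
    time_s = rep(result@time, each = nE),
    edge_id = rep(rownames(result@flows), nT),
    Q_m3s = as.vector(result@flows),
    tau_Pa = as.vector(result@wss))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write metrics as tidy CSV (entity_id, metric, value, units)
#'
#' @param metrics a [HemodynamicMetrics-class].
#' @param path output file.
#' @export
writeMetricsCSV <- function(metrics, path) {
  et <- metrics@edgeTable
  rows <- rbind(
    data.frame(entity_id = et$edge_id, metric = "tawss", value = et$tawss_Pa,
               units = "Pa"),
    data.frame(entity_id = et$edge_id, metric = "osi", value = et$osi,
               units = ""),
    data.frame(entity_id = et$edge_id, metric = "mean_velocity",
               value = et$mean_velocity_m_s, units = "m/s"))
  st <- metrics@sacTable
  if (nrow(st) > 0)
    rows <- rbind(rows,
      data.frame(entity_id = st$label, metric = "nir_mean",
                 value = st$nir_mean_mls, units = "ml/s"),
      data.frame(entity_id = st$label, metric = "wss_proxy_mean",
                 value = st$wss_proxy_mean_Pa, units = "Pa"),
      data.frame(entity_id = st$label, metric = "wss_proxy_max",
                 value = st$wss_proxy_max_Pa, units = "Pa"),
      data.frame(entity_id = st$label, metric = "osi", value = st$osi,
                 units = ""))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as JSON
#'
#' @param report a [ComparisonReport-class].
#' @param path output file.
#' @export
writeComparisonJSON <- function(report, path) {
  obj <- list(
    sign_convention = "delta = complex - trimmed",
    cases = report@cases,
    summary = report@summary,
    max_abs_centerline_delta_m_s = report@maxAbsPathDiff,
    path_differences = report@pathDiffs)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
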