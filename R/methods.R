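## Accessors and show methods.

#' @rdname cowflow-generics
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname cowflow-generics
#' @export
setMethod("voxelData", "SegmentationMask", function(x) x@mask)
#' @rdname cowflow-generics
#' @export
setMethod("voxelData", "GroundTruth", function(x) x@mask)
#' @rdname cowflow-generics
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname cowflow-generics
#' @export
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname cowflow-generics
#' @export
setMethod("voxelSpacing", "GroundTruth", function(x) x@spacing)
#' @rdname cowflow-generics
#' @export
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)
#' @rdname cowflow-generics
#' @export
setMethod("voxelOrigin", "SegmentationMask", function(x) x@origin)
#' @rdname cowflow-generics
#' @export
setMethod("voxelOrigin", "GroundTruth", function(x) x@origin)

#' @rdname cowflow-generics
#' @export
setMethod("networkNodes", "VesselNetwork", function(x) x@nodes)
#' @rdname cowflow-generics
#' @export
setMethod("networkEdges", "VesselNetwork", function(x) x@edges)
#' @rdname cowflow-generics
#' @export
setMethod("inletNodes", "VesselNetwork",
          function(x) x@nodes[x@nodes$kind == "inlet", , drop = FALSE])
#' @rdname cowflow-generics
#' @export
setMethod("outletNodes", "VesselNetwork",
          function(x) x@nodes[x@nodes$kind == "outlet", , drop = FALSE])

#' @rdname cowflow-generics
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname cowflow-generics
#' @export
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)
#' @rdname cowflow-generics
#' @export
setMethod("meshOpenings", "SurfaceMesh", function(x) x@openings)

#' @rdname cowflow-generics
#' @export
setMethod("waveformFlow", "FlowWaveform", function(x) x@flow)
#' @rdname cowflow-generics
#' @export
setMethod("waveformTime", "FlowWaveform",
          function(x) seq(0, x@period, length.out = length(x@flow)))
#' @rdname cowflow-generics
#' @export
setMethod("meanFlow", "FlowWaveform",
          function(x) mean(x@flow[-length(x@flow)]))

#' @rdname cowflow-generics
#' @export
setMethod("edgeFlows", "SimulationResult", function(x) x@flows)
#' @rdname cowflow-generics
#' @export
setMethod("nodePressures", "SimulationResult", function(x) x@pressures)
#' @rdname cowflow-generics
#' @export
setMethod("edgeShear", "SimulationResult", function(x) x@wss)
#' @rdname cowflow-generics
#' @export
setMethod("timeGrid", "SimulationResult", function(x) x@time)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %.3g mm\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("SegmentationMask: %d x %d x %d voxels, %d foreground (%.2f%%), %d seed(s)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask), nrow(object@seeds)))
})

setMethod("show", "VesselNetwork", function(object) {
  nd <- object@nodes
  cat(sprintf("VesselNetwork: %d nodes, %d edges\n", nrow(nd), nrow(object@edges)))
  cat(sprintf("  inlets: %s\n",
              paste(nd$label[nd$kind == "inlet"], collapse = ", ")))
  cat(sprintf("  outlets: %d, aneurysm sacs: %d\n",
              sum(nd$kind == "outlet"), sum(nd$kind == "aneurysm_sac")))
  cat(sprintf("  radius range [%.3g, %.3g] mm, total length %.4g mm\n",
              min(object@edges$radius), max(object@edges$radius),
              sum(object@edges$length)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles, %d labelled opening(s)\n",
              nrow(object@vertices), nrow(object@triangles),
              nrow(object@openings)))
})

setMethod("show", "FlowWaveform", function(object) {
  cat(sprintf("FlowWaveform '%s': period %.3g s, %d samples, mean %.4g l/s\n",
              object@label, object@period, length(object@flow),
              meanFlow(object)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d edges x %d time steps (evaluated cycle)\n",
              nrow(object@flows), length(object@time)))
  cat(sprintf("  max |Q| %.4g m^3/s, interior-node residual %.3g m^3/s\n",
              max(abs(object@flows)), object@residual))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport (%s vs %s), deltas = complex - trimmed:\n",
              object@cases[1], object@cases[2]))
  print(object@summary, row.names = FALSE)
  cat(sprintf("  max |delta CL-v| = %.4g m/s\n", object@maxAbsPathDiff))
})
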