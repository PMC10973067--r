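#' @title Generics for cowflow data classes
#' @description Accessor and operation generics shared across the package's
#'   S4 classes.
#' @param x,object an object of one of the cowflow S4 classes.
#' @param ... further arguments passed to methods.
#' @name cowflow-generics
#' @keywords internal
NULL

#' @rdname cowflow-generics
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname cowflow-generics
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname cowflow-generics
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname cowflow-generics
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname cowflow-generics
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname cowflow-generics
#' @export
setGeneric("inletNodes", function(x) standardGeneric("inletNodes"))

#' @rdname cowflow-generics
#' @export
setGeneric("outletNodes", function(x) standardGeneric("outletNodes"))

#' @rdname cowflow-generics
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname cowflow-generics
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @rdname cowflow-generics
#' @export
setGeneric("meshOpenings", function(x) standardGeneric("meshOpenings"))

#' @rdname cowflow-generics
#' @export
setGeneric("waveformFlow", function(x) standardGeneric("waveformFlow"))

#' @rdname cowflow-generics
#' @export
setGeneric("waveformTime", function(x) standardGeneric("waveformTime"))

#' @rdname cowflow-generics
#' @export
setGeneric("meanFlow", function(x) standardGeneric("meanFlow"))

#' @rdname cowflow-generics
#' @export
setGeneric("edgeFlows", function(x) standardGeneric("edgeFlows"))

#' @rdname cowflow-generics
#' @export
setGeneric("nodePressures", function(x) standardGeneric("nodePressures"))

#' @rdname cowflow-generics
#' @export
setGeneric("edgeShear", function(x) standardGeneric("edgeShear"))

#' @rdname cowflow-generics
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))
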