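## Central S4 data classes. World coordinates are millimetres throughout;
## voxel index (i, j, k) (1-based in R) maps to world position
## origin + (index - 1) * spacing (voxel-center convention).

#' ImageVolume: a 3D scalar intensity grid with isotropic spacing
#'
#' Container for angiography-like image volumes. Intensities are arbitrary
#' units; spacing is millimetres and identical along the three axes.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing isotropic voxel spacing in mm.
#' @slot origin world position (mm) of the center of voxel (1, 1, 1).
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = 0.32, origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3D array")
  if (any(d < 16)) return("grid must have at least 16 voxels per axis")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@origin) != 3) return("origin must have length 3")
  if (!all(is.finite(object@data))) return("all intensities must be finite")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing isotropic voxel spacing (mm), default 0.32 as for
#'   high-resolution time-of-flight angiography.
#' @param origin world coordinates (mm) of the first voxel center.
#' @return An [ImageVolume-class] object.
#' @export
imageVolume <- function(data, spacing = 0.32, origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = spacing, origin = as.numeric(origin))
}

#' SegmentationMask: a binary lumen mask tied to its source grid
#'
#' @slot mask 3D logical array.
#' @slot spacing voxel spacing (mm), copied from the source volume.
#' @slot origin origin (mm), copied from the source volume.
#' @slot seeds integer matrix (n x 3) of 1-based seed voxel indices.
#' @slot boundaryLevel the intensity level (as a fraction of the
#'   lumen-background contrast) at which the mask boundary sits: 0.5 for a
#'   half-maximum mask, 1 - tolerance for a relative-band region growing.
#'   Radius estimation uses it to undo the sub-voxel boundary bias.
#' @export
setClass("SegmentationMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 seeds = "matrix", boundaryLevel = "numeric"),
  prototype(boundaryLevel = 0.5)
)

setValidity("SegmentationMask", function(object) {
  if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@spacing <= 0) return("spacing must be positive")
  if (ncol(object@seeds) != 3) return("seeds must be an n x 3 matrix")
  TRUE
})

#' GroundTruth: the generator's exact lumen geometry
#'
#' Produced alongside rasterized volumes so that segmentation and centerline
#' recovery can be scored against a known answer.
#'
#' @slot mask 3D logical array, the exact noise-free lumen indicator.
#' @slot spacing,origin grid geometry (mm), identical to the paired volume.
#' @slot centerlines named list of n x 3 matrices (mm), one polyline per edge.
#' @slot radii named numeric vector of true per-edge radii (mm).
#' @export
setClass("GroundTruth",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 centerlines = "list", radii = "numeric")
)

setValidity("GroundTruth", function(object) {
  if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
  if (length(object@centerlines) != length(object@radii))
    return("centerlines and radii must describe the same edges")
  TRUE
})

#' VesselNetwork: a graph of vessel segments
#'
#' The central geometric object: nodes carry positions (mm) and a kind
#' (inlet, outlet, junction, internal or aneurysm_sac); edges carry length
#' (mm), radius (mm) and a kind (vessel or neck). Aneurysm sacs additionally
#' carry a volume (mm^3) and a compliance (m^3/Pa) on their node row.
#'
#' @slot nodes data.frame with columns id, x, y, z, kind, label and (for
#'   sacs) sac_volume_mm3, sac_compliance_m3_per_Pa.
#' @slot edges data.frame with columns id, from, to, length, radius, kind.
#' @slot metadata list of provenance information (units, generator call).
#' @export
setClass("VesselNetwork",
  representation(nodes = "data.frame", edges = "data.frame", metadata = "list")
)

.network_degrees <- function(object) {
  tab <- table(factor(c(object@edges$from, object@edges$to),
                      levels = object@nodes$id))
  as.integer(tab)
}

setValidity("VesselNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  need_n <- c("id", "x", "y", "z", "kind", "label")
  if (!all(need_n %in% names(nd))) return("nodes lack required columns")
  need_e <- c("id", "from", "to", "length", "radius", "kind")
  if (!all(need_e %in% names(ed))) return("edges lack required columns")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (nrow(ed) > 0 && anyDuplicated(ed$id)) return("duplicate edge ids")
  if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
    return("edge endpoints must be node ids")
  if (any(ed$radius <= 0)) return("all radii must be > 0")
  if (any(ed$length <= 0)) return("all lengths must be > 0")
  pos <- as.matrix(nd[, c("x", "y", "z")])
  rownames(pos) <- nd$id
  if (nrow(ed) > 0) {
    eu <- sqrt(rowSums((pos[as.character(ed$from), , drop = FALSE] -
                        pos[as.character(ed$to), , drop = FALSE])^2))
    if (any(ed$length < eu - 1e-6))
      return("edge length must be >= Euclidean endpoint distance")
  }
  deg <- .network_degrees(object)
  if (nrow(ed) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from), to = as.character(ed$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nd$id)))
    if (igraph::components(g)$no != 1) return("graph must be connected")
  }
  boundary <- nd$kind %in% c("inlet", "outlet")
  if (any(deg[boundary] != 1))
    return("every inlet and outlet node must have degree exactly 1")
  sacs <- which(nd$kind == "aneurysm_sac")
  for (s in sacs) {
    inc <- ed$from == nd$id[s] | ed$to == nd$id[s]
    if (sum(inc) != 1 || any(ed$kind[inc] != "neck"))
      return("an aneurysm sac must connect through exactly one neck edge")
    if (!isTRUE(nd$sac_volume_mm3[s] > 0))
      return("sac volume must be > 0")
    if (!isTRUE(nd$sac_compliance_m3_per_Pa[s] > 0))
      return("sac compliance must be > 0")
  }
  TRUE
})

#' Construct a VesselNetwork
#'
#' @param nodes,edges data.frames as described in [VesselNetwork-class].
#' @param metadata optional provenance list.
#' @return A validated [VesselNetwork-class] object.
#' @export
vesselNetwork <- function(nodes, edges, metadata = list()) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  if (is.null(nodes$sac_volume_mm3)) nodes$sac_volume_mm3 <- NA_real_
  if (is.null(nodes$sac_compliance_m3_per_Pa))
    nodes$sac_compliance_m3_per_Pa <- NA_real_
  if (is.null(metadata$units))
    metadata$units <- list(position = "mm", length = "mm", radius = "mm",
                           sac_volume = "mm3", sac_compliance = "m3/Pa")
  new("VesselNetwork", nodes = nodes, edges = edges, metadata = metadata)
}

#' FlowWaveform: one cardiac period of volumetric inlet flow
#'
#' Samples are uniform over one period including both endpoints, whose values
#' agree (periodicity). Flow is litres per second, matching how inlet flows
#' are reported for phase-contrast MRI measurements.
#'
#' @slot period cardiac period in seconds.
#' @slot flow numeric vector of volumetric flow samples (l/s); first and last
#'   samples are equal.
#' @slot label inlet label this waveform belongs to ("ICAl", "ICAr", "BA").
#' @export
setClass("FlowWaveform",
  representation(period = "numeric", flow = "numeric", label = "character")
)

setValidity("FlowWaveform", function(object) {
  if (object@period <= 0) return("period must be > 0")
  if (length(object@flow) < 50) return("need at least 50 samples per period")
  if (abs(object@flow[1] - object@flow[length(object@flow)]) > 1e-9)
    return("first and last samples must agree (periodic waveform)")
  if (meanFlow(object) <= 0) return("mean flow must be > 0 for an inlet")
  TRUE
})

#' AneurysmSpec: parameters of a saccular aneurysm to attach
#'
#' @slot edgeId id of the parent vessel edge.
#' @slot arcPosition fractional position (0..1) along the parent edge.
#' @slot neckRadius neck radius (mm), at most the parent radius.
#' @slot neckLength effective neck length (mm).
#' @slot sacVolume sac volume (mm^3).
#' @slot compliance sac compliance (m^3/Pa).
#' @slot label identifier, e.g. "IA-A".
#' @export
setClass("AneurysmSpec",
  representation(edgeId = "character", arcPosition = "numeric",
                 neckRadius = "numeric", neckLength = "numeric",
                 sacVolume = "numeric", compliance = "numeric",
                 label = "character")
)

setValidity("AneurysmSpec", function(object) {
  if (object@arcPosition < 0 || object@arcPosition > 1)
    return("arcPosition must lie in [0, 1]")
  if (object@neckRadius <= 0) return("neck radius must be > 0")
  if (object@sacVolume <= 0) return("sac volume must be > 0")
  if (object@compliance <= 0) return("compliance must be > 0")
  if (object@neckLength <= 0) return("neck length must be > 0")
  TRUE
})

#' SurfaceMesh: a triangulated vessel surface
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot openings data.frame of per-opening metadata (id, label, kind,
#'   centroid cx/cy/cz, normal nx/ny/nz, area_mm2); empty before end-cutting.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 openings = "data.frame")
)

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3) return("triangles must be m x 3")
  t <- object@triangles
  if (nrow(t) > 0 && (min(t) < 1 || max(t) > nrow(object@vertices)))
    return("triangle indices out of range")
  TRUE
})

#' FrangiConfig: multiscale vesselness filter parameters
#'
#' @slot scales Gaussian scales (voxel units), default 1..6.
#' @slot alpha plate-vs-line sensitivity (dimensionless), default 0.5.
#' @slot beta blob suppression sensitivity (dimensionless), default 0.5.
#' @slot c structure-norm sensitivity; NA selects half the maximum Hessian
#'   norm per scale (the filter's conventional default).
#' @slot brightOnDark TRUE for bright vessels on dark background.
#' @export
setClass("FrangiConfig",
  representation(scales = "numeric", alpha = "numeric", beta = "numeric",
                 c = "numeric", brightOnDark = "logical"),
  prototype(scales = 1:6, alpha = 0.5, beta = 0.5, c = NA_real_,
            brightOnDark = TRUE)
)

setValidity("FrangiConfig", function(object) {
  if (length(object@scales) == 0 || any(object@scales <= 0))
    return("scales must be a non-empty positive vector")
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be > 0")
  if (!is.na(object@c) && object@c <= 0) return("c must be > 0 (or NA)")
  TRUE
})

#' @rdname FrangiConfig-class
#' @param scales,alpha,beta,c,brightOnDark see slots.
#' @export
frangiConfig <- function(scales = 1:6, alpha = 0.5, beta = 0.5, c = NA_real_,
                         brightOnDark = TRUE) {
  new("FrangiConfig", scales = as.numeric(scales), alpha = alpha, beta = beta,
      c = c, brightOnDark = brightOnDark)
}

#' FluidProperties: Newtonian blood parameters
#'
#' Defaults are the standard values for blood treated as an incompressible
#' Newtonian fluid: dynamic viscosity 4 mPa s, density 1055 kg/m^3.
#'
#' @slot mu dynamic viscosity (Pa s).
#' @slot rho density (kg/m^3).
#' @export
setClass("FluidProperties",
  representation(mu = "numeric", rho = "numeric"),
  prototype(mu = 0.004, rho = 1055)
)

setValidity("FluidProperties", function(object) {
  if (object@mu <= 0 || object@rho <= 0) return("mu and rho must be > 0")
  TRUE
})

#' @rdname FluidProperties-class
#' @param mu,rho see slots.
#' @export
fluidProperties <- function(mu = 0.004, rho = 1055) {
  new("FluidProperties", mu = mu, rho = rho)
}

#' SolverConfig: time discretization and outlet-splitting parameters
#'
#' Defaults follow the pulsatile simulation protocol: 1 ms time steps over
#' three cardiac cycles with only the last cycle evaluated, and Murray's-law
#' outlet splitting with exponent n = 2.
#'
#' @slot dt time step (s).
#' @slot cycles number of cardiac cycles simulated.
#' @slot murrayN Murray splitting exponent.
#' @slot referenceNode node id held at zero pressure (empty = first outlet).
#' @slot splitMode "global" (fractions of total instantaneous inflow) or
#'   "perBranch" (fractions within each inlet's downstream branch).
#' @export
setClass("SolverConfig",
  representation(dt = "numeric", cycles = "numeric", murrayN = "numeric",
                 referenceNode = "character", splitMode = "character"),
  prototype(dt = 0.001, cycles = 3, murrayN = 2, referenceNode = character(0),
            splitMode = "global")
)

setValidity("SolverConfig", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (object@cycles < 1) return("cycles must be >= 1")
  if (object@murrayN <= 0) return("murrayN must be > 0")
  if (!object@splitMode %in% c("global", "perBranch"))
    return("splitMode must be 'global' or 'perBranch'")
  TRUE
})

#' @rdname SolverConfig-class
#' @param dt,cycles,murrayN,referenceNode,splitMode see slots.
#' @export
solverConfig <- function(dt = 0.001, cycles = 3, murrayN = 2,
                         referenceNode = character(0), splitMode = "global") {
  new("SolverConfig", dt = dt, cycles = cycles, murrayN = murrayN,
      referenceNode = as.character(referenceNode), splitMode = splitMode)
}

#' SimulationResult: per-edge flows and shear, nodal pressures over a cycle
#'
#' Stores the evaluated (last) cardiac cycle on a uniform time grid without a
#' duplicated endpoint: times t0, t0 + dt, ..., t0 + period - dt. Flows are
#' signed along the stored edge orientation (m^3/s); pressures are relative
#' to the reference node (Pa); tau is the Poiseuille wall shear 4 mu Q /
#' (pi r^3) (Pa).
#'
#' @slot time time grid (s) of the evaluated cycle.
#' @slot flows edges x time matrix of signed flows (m^3/s), edge ids as rownames.
#' @slot pressures nodes x time matrix (Pa), node ids as rownames.
#' @slot wss edges x time matrix of wall shear (Pa).
#' @slot sacPressures sacs x time matrix (Pa).
#' @slot sacFlows sacs x time matrix of neck flows into each sac (m^3/s).
#' @slot network the VesselNetwork that was solved.
#' @slot config the SolverConfig used.
#' @slot residual maximum interior-node flow residual over the cycle (m^3/s).
#' @export
setClass("SimulationResult",
  representation(time = "numeric", flows = "matrix", pressures = "matrix",
                 wss = "matrix", sacPressures = "matrix", sacFlows = "matrix",
                 network = "VesselNetwork", config = "SolverConfig",
                 residual = "numeric")
)

#' PlaneSample: velocity samples on a vessel cross-section
#'
#' Radial samples of the axial velocity profile (m/s) on a circular plane,
#' together with the plane area and instantaneous volumetric flow, as needed
#' for normalized velocity profiles. Radial positions and quadrature weights
#' follow a Gauss-Legendre rule so that the area-weighted mean of the
#' sampled profile reproduces Q/A to quadrature accuracy.
#'
#' @slot radius vessel radius (m).
#' @slot r radial sample positions (m).
#' @slot weights quadrature weights (m^2) summing to the plane area.
#' @slot velocity n_radial x n_time matrix of axial velocities (m/s).
#' @slot Q instantaneous volumetric flow (m^3/s) per time sample.
#' @slot time time grid (s).
#' @export
setClass("PlaneSample",
  representation(radius = "numeric", r = "numeric", weights = "numeric",
                 velocity = "matrix", Q = "numeric", time = "numeric")
)

setValidity("PlaneSample", function(object) {
  if (object@radius <= 0) return("radius must be > 0")
  if (length(object@Q) != ncol(object@velocity))
    return("Q and velocity time dimensions disagree")
  TRUE
})

#' HemodynamicMetrics: evaluated hemodynamic quantities for one simulation
#'
#' @slot edgeTable data.frame: edge_id, tawss_Pa, osi, mean_velocity_m_s.
#' @slot sacTable data.frame per sac: label, nir_mean_mls, wss_proxy_mean_Pa,
#'   wss_proxy_max_Pa, osi.
#' @slot sacSeries list per sac of data.frames (time_s, nir_mls, wss_proxy_Pa).
#' @slot paths list per centerline path of data.frames (arclength_mm,
#'   velocity_m_s, distal_to_outlet).
#' @slot caseId identifier of the simulated case.
#' @export
setClass("HemodynamicMetrics",
  representation(edgeTable = "data.frame", sacTable = "data.frame",
                 sacSeries = "list", paths = "list", caseId = "character")
)

#' ComparisonReport: paired complex-vs-trimmed metric deltas
#'
#' All deltas follow the single declared sign convention
#' delta X = X_complex - X_trimmed.
#'
#' @slot summary data.frame of scalar deltas (metric, complex, trimmed, delta).
#' @slot pathDiffs list per path of data.frames (arclength_mm, v_complex,
#'   v_trimmed, delta_v).
#' @slot maxAbsPathDiff maximum |delta centerline velocity| (m/s).
#' @slot cases character(2): the paired case ids (complex, trimmed).
#' @export
setClass("ComparisonReport",
  representation(summary = "data.frame", pathDiffs = "list",
                 maxAbsPathDiff = "numeric", cases = "character")
)

#' StudyConfig: full four-case study configuration
#'
#' Bundles every stage parameter of the complex-versus-trimmed study:
#' phantom, segmentation, trimming, aneurysm placement, fluid, solver and
#' inflow settings, plus the global seed.
#'
#' @slot nOutlets outlet count of the complex model (default 60).
#' @slot keep outlet count of the trimmed model (default 10).
#' @slot seed global random seed.
#' @slot spacing voxel spacing (mm) for the imaging stage.
#' @slot noiseSd additive image noise (a.u.).
#' @slot lumenIntensity,backgroundIntensity phantom contrast (a.u.).
#' @slot tolerance region-growing admission tolerance (fraction of seed
#'   intensity, default 0.02).
#' @slot skipImaging if TRUE the simulations run on the template network
#'   directly, bypassing rasterization and segmentation.
#' @slot period,pulsatility,nSamples inlet waveform parameters.
#' @slot fluid FluidProperties.
#' @slot solver SolverConfig.
#' @slot aneurysms list of parameters for [makeAneurysmSpec()] (default one
#'   sac on the right MCA, one on the left MCA).
#' @export
setClass("StudyConfig",
  representation(nOutlets = "numeric", keep = "numeric", seed = "numeric",
                 spacing = "numeric", noiseSd = "numeric",
                 lumenIntensity = "numeric", backgroundIntensity = "numeric",
                 tolerance = "numeric", skipImaging = "logical",
                 period = "numeric", pulsatility = "numeric",
                 nSamples = "numeric", fluid = "FluidProperties",
                 solver = "SolverConfig", aneurysms = "list")
)
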