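## Rasterize a vessel network into an angiography-like intensity volume.

#' Rasterize a vessel network into a synthetic angiography volume
#'
#' Renders every vessel edge as a capsule (cylinder with spherical caps) of
#' its stored radius into an isotropic voxel grid. Voxels whose centers lie
#' inside the lumen receive the lumen intensity; partial-volume mixing at the
#' boundary is modelled by supersampling the lumen indicator 3x per axis and
#' box-averaging. Optional additive zero-mean Gaussian noise is reproducible
#' from the seed. The paired [GroundTruth-class] carries the exact noise-free
#' lumen mask (voxel centers inside the lumen), the edge centerlines and the
#' true per-edge radii.
#'
#' @param network a [VesselNetwork-class]. Neck edges and aneurysm sacs are
#'   not rasterized (the sac is a lumped element, not a meshed geometry).
#' @param spacing isotropic voxel spacing (mm), default 0.32 as in
#'   high-resolution time-of-flight angiography.
#' @param lumenIntensity,backgroundIntensity intensities (a.u.).
#' @param noiseSd additive Gaussian noise standard deviation (a.u.).
#' @param seed integer seed for the noise; same inputs and seed give
#'   bit-identical volumes.
#' @param margin empty border around the network, in voxels.
#' @param maxVoxels resource budget: grids larger than this raise an error.
#' @param supersample partial-volume supersampling factor per axis.
#' @return list with elements \code{volume} ([ImageVolume-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' net <- generateCowTemplate(nOutlets = 6, seed = 1)
#' ph <- rasterizeNetwork(net, spacing = 0.6, noiseSd = 0, seed = 1)
#' ph$volume
#' @export
rasterizeNetwork <- function(network, spacing = 0.32, lumenIntensity = 100,
                             backgroundIntensity = 0, noiseSd = 0, seed = 1,
                             margin = 8, maxVoxels = 220^3, supersample = 3) {
  stopifnot(is(network, "VesselNetwork"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (lumenIntensity <= backgroundIntensity)
    stop("lumenIntensity must exceed backgroundIntensity")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  keep <- network@edges$kind == "vessel"
  segs <- .edge_segments(network)[keep, , drop = FALSE]
  lo <- apply(rbind(segs[, 1:3], segs[, 4:6]), 2, min) - segs[1, 7] * 0 -
    max(segs[, 7]) - margin * spacing
  hi <- apply(rbind(segs[, 1:3], segs[, 4:6]), 2, max) +
    max(segs[, 7]) + margin * spacing
  dim3 <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  dim3 <- pmax(dim3, 16L)
  if (prod(as.numeric(dim3)) > maxVoxels)
    stop(sprintf(
      "grid %d x %d x %d (%.3g voxels) exceeds the voxel budget of %.3g; increase spacing or the budget",
      dim3[1], dim3[2], dim3[3], prod(as.numeric(dim3)), maxVoxels))
  origin <- as.numeric(lo)
  ras <- .rasterize_capsules(segs, dim3, spacing, origin, as.integer(supersample))
  vol <- backgroundIntensity + (lumenIntensity - backgroundIntensity) * ras$frac
  if (noiseSd > 0) {
    noise <- .with_seed(seed, rnorm(length(vol), 0, noiseSd))
    vol <- vol + noise
  }
  dim(vol) <- dim3
  centerlines <- lapply(seq_len(nrow(segs)), function(i)
    rbind(segs[i, 1:3], segs[i, 4:6]))
  names(centerlines) <- network@edges$id[keep]
  radii <- setNames(segs[, 7], network@edges$id[keep])
  mask <- ras$mask
  dim(mask) <- dim3
  truth <- new("GroundTruth", mask = mask, spacing = spacing, origin = origin,
               centerlines = centerlines, radii = radii)
  list(volume = imageVolume(vol, spacing = spacing, origin = origin),
       truth = truth)
}

#' World-to-voxel and voxel-to-world index conversion
#'
#' Voxel index (1, 1, 1) maps to the origin; world = origin +
#' (index - 1) * spacing.
#'
#' @param x an object with a voxel grid (ImageVolume, SegmentationMask or
#'   GroundTruth).
#' @param points n x 3 matrix of world coordinates (mm) or voxel indices.
#' @return n x 3 matrix.
#' @export
worldToVoxel <- function(x, points) {
  points <- rbind(points)
  sweep(points, 2, voxelOrigin(x)) / voxelSpacing(x) + 1
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(x, points) {
  points <- rbind(points)
  sweep((points - 1) * voxelSpacing(x), 2, voxelOrigin(x), "+")
}
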