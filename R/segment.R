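## Seeded region growing and component cleanup.

#' Seeded region growing with a relative intensity band
#'
#' Breadth-first flood fill over 26-neighborhoods. A voxel is admitted iff
#' it is connected to a seed through admitted voxels and its intensity lies
#' within \code{tolerance} (default 2\%) of that seed's intensity,
#' \eqn{|I(v) - I_{ref}| \le tol \cdot I_{ref}}. Bands are static and
#' per-seed (each seed floods with its own reference; the mask is the union
#' over seeds), so the result is deterministic and independent of traversal
#' order.
#'
#' @param volume an [ImageVolume-class].
#' @param seeds n x 3 matrix of 1-based voxel indices (one row per seed).
#' @param tolerance admission band as a fraction of the seed intensity,
#'   default 0.02.
#' @return A [SegmentationMask-class] carrying the seed list.
#' @export
regionGrow <- function(volume, seeds, tolerance = 0.02) {
  stopifnot(is(volume, "ImageVolume"))
  seeds <- rbind(seeds)
  storage.mode(seeds) <- "integer"
  if (nrow(seeds) < 1) stop("need at least one seed")
  if (tolerance <= 0 || tolerance >= 1)
    stop("tolerance must lie in (0, 1)")
  d <- dim(volume@data)
  mask <- .region_grow(as.numeric(volume@data), d, seeds, tolerance)
  dim(mask) <- d
  if (sum(mask) <= nrow(seeds))
    warning("no voxel admitted beyond the seeds; returning seeds-only mask")
  new("SegmentationMask", mask = mask, spacing = volume@spacing,
      origin = volume@origin, seeds = seeds,
      boundaryLevel = 1 - tolerance)
}

#' Remove unconnected components from a mask or mesh
#'
#' For a [SegmentationMask-class], keeps only the 26-connected components
#' that contain a seed (the automated counterpart of excluding artifacts
#' and unconnected parts by hand). For a [SurfaceMesh-class], keeps the
#' connected component with the largest surface area.
#'
#' @param x a [SegmentationMask-class] or [SurfaceMesh-class].
#' @param seeds optional n x 3 seed matrix overriding the mask's own seeds.
#' @return An object of the same class.
#' @export
cleanComponents <- function(x, seeds = NULL) {
  if (is(x, "SegmentationMask")) {
    s <- if (is.null(seeds)) x@seeds else rbind(seeds)
    storage.mode(s) <- "integer"
    d <- dim(x@mask)
    lab <- .label_components(x@mask, d)
    seedLabs <- unique(lab[cbind(s[, 1], s[, 2], s[, 3])])
    seedLabs <- seedLabs[seedLabs > 0]
    if (length(seedLabs) == 0)
      stop("no connected component contains a seed")
    keep <- array(lab %in% seedLabs, dim = d)
    new("SegmentationMask", mask = keep, spacing = x@spacing,
        origin = x@origin, seeds = x@seeds, boundaryLevel = x@boundaryLevel)
  } else if (is(x, "SurfaceMesh")) {
    .mesh_largest_component(x)
  } else stop("cleanComponents expects a SegmentationMask or SurfaceMesh")
}

#' Full segmentation chain for a phantom volume
#'
#' Optionally presmooths the volume (noise control), grows a mask from the
#' seeds with the relative-band criterion and removes unconnected
#' components. By default growing operates on the intensity volume; with
#' \code{useVesselness = TRUE} it operates on the multiscale vesselness
#' intermediate instead (the admission band then applies to vesselness
#' values, which vary strongly across the lumen, so the intensity route is
#' the default).
#'
#' @param volume an [ImageVolume-class].
#' @param seeds n x 3 matrix of 1-based voxel indices.
#' @param tolerance admission band, default 0.02.
#' @param presmoothSigma Gaussian presmoothing in voxels (0 = off).
#' @param useVesselness grow on the vesselness intermediate instead of the
#'   intensity volume.
#' @param frangi a [FrangiConfig-class] for the vesselness route.
#' @return A cleaned [SegmentationMask-class].
#' @export
segmentVolume <- function(volume, seeds, tolerance = 0.02,
                          presmoothSigma = 0, useVesselness = FALSE,
                          frangi = frangiConfig()) {
  ref <- if (presmoothSigma > 0) smoothVolume(volume, presmoothSigma) else volume
  if (useVesselness) ref <- vesselnessMultiscale(ref, frangi)
  mask <- regionGrow(ref, seeds, tolerance)
  cleanComponents(mask)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays or objects with a voxel mask.
#' @return the Dice coefficient 2|A&B| / (|A| + |B|).
#' @export
diceCoefficient <- function(a, b) {
  if (!is.array(a)) a <- voxelData(a)
  if (!is.array(b)) b <- voxelData(b)
  .dice(a, b)
}
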