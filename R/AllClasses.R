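#' @import methods
NULL

#' Physical voxel spacing of a z-stack
#'
#' Holds the physical size of one voxel along each axis, in micrometres.
#' Every physical quantity in the package (radii, lengths, volumes,
#' distances) is derived from voxel index differences multiplied by these
#' spacings; voxels are treated as centered on a 0-based physical grid, so
#' voxel index \code{(z, y, x)} (1-based in R) sits at physical position
#' \code{((x-1)*dx, (y-1)*dy, (z-1)*dz)}.
#'
#' @slot dx in-plane pixel size along x (micrometres)
#' @slot dy in-plane pixel size along y (micrometres)
#' @slot dz axial step between planes (micrometres)
#' @export
setClass("VoxelSpacing",
  representation(dx = "numeric", dy = "numeric", dz = "numeric"),
  prototype(dx = 0.98, dy = 0.98, dz = 5),
  validity = function(object) {
    if (length(object@dx) != 1L || length(object@dy) != 1L ||
        length(object@dz) != 1L)
      return("dx, dy, dz must each have length 1")
    if (!all(is.finite(c(object@dx, object@dy, object@dz))) ||
        any(c(object@dx, object@dy, object@dz) <= 0))
      return("all spacings must be strictly positive and finite")
    TRUE
  })

#' Construct a VoxelSpacing
#'
#' Defaults match the acquisition sampling the pipeline targets: 0.98 um
#' in-plane pixels and a 5 um axial step.
#'
#' @param dx,dy,dz voxel edge lengths in micrometres
#' @return a \linkS4class{VoxelSpacing}
#' @examples
#' voxelSpacing()                 # 0.98 x 0.98 x 5 um
#' voxelSpacing(1, 1, 1)          # isotropic unit grid
#' @export
voxelSpacing <- function(dx = 0.98, dy = 0.98, dz = 5) {
  new("VoxelSpacing", dx = as.numeric(dx), dy = as.numeric(dy),
      dz = as.numeric(dz))
}

#' One channel of a 3D microscopy stack
#'
#' Voxel intensities for a single channel, stored as a numeric array with
#' \code{dim = c(nz, ny, nx)} (plane index first, shallowest plane at z = 1),
#' together with physical spacing and session metadata.
#'
#' @slot voxels numeric array (nz, ny, nx) of nonnegative intensities
#' @slot spacing \linkS4class{VoxelSpacing}
#' @slot channel one of \code{"vessel"}, \code{"plaque"}, \code{"thg"}
#' @slot sessionId free-form session identifier
#' @slot bitDepthMax maximum representable intensity (255 for 8-bit data,
#'   65535 for 16-bit)
#' @export
setClass("ImageStack",
  representation(voxels = "array", spacing = "VoxelSpacing",
                 channel = "character", sessionId = "character",
                 bitDepthMax = "numeric"),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3L) return("voxels must be a 3D array (nz, ny, nx)")
    if (any(d < 1L)) return("every axis must have extent >= 1")
    if (!object@channel %in% c("vessel", "plaque", "thg"))
      return("channel must be one of 'vessel', 'plaque', 'thg'")
    if (length(object@bitDepthMax) != 1L || object@bitDepthMax <= 0)
      return("bitDepthMax must be a single positive number")
    rng <- range(object@voxels)
    if (!all(is.finite(rng))) return("voxel intensities must be finite")
    if (rng[1] < 0) return("voxel intensities must be nonnegative")
    if (rng[2] > object@bitDepthMax)
      return("voxel intensities must not exceed bitDepthMax")
    TRUE
  })

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array, dim (nz, ny, nx)
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param channel \code{"vessel"}, \code{"plaque"} or \code{"thg"}
#' @param sessionId session identifier string
#' @param bitDepthMax maximum representable intensity; default 65535 (16-bit)
#' @return an \linkS4class{ImageStack}
#' @export
imageStack <- function(voxels, spacing = voxelSpacing(), channel = "vessel",
                       sessionId = "s1", bitDepthMax = 65535) {
  new("ImageStack", voxels = voxels, spacing = spacing, channel = channel,
      sessionId = sessionId, bitDepthMax = as.numeric(bitDepthMax))
}

#' Binary segmentation mask over a stack
#'
#' @slot voxels integer array (nz, ny, nx) with values in {0, 1}
#' @slot spacing \linkS4class{VoxelSpacing}
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "VoxelSpacing"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array (nz, ny, nx)")
    v <- object@voxels
    if (!all(v == 0 | v == 1)) return("mask values must be strictly 0 or 1")
    TRUE
  })

#' Construct a BinaryMask
#'
#' Any nonzero voxel is mapped to 1.
#'
#' @param voxels 3D array; nonzero entries become foreground
#' @param spacing a \linkS4class{VoxelSpacing}
#' @return a \linkS4class{BinaryMask}
#' @export
binaryMask <- function(voxels, spacing = voxelSpacing()) {
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  new("BinaryMask", voxels = v, spacing = spacing)
}

#' Labeled 3D component volume
#'
#' Integer labels 1..K identify 3D-connected components; 0 is background.
#'
#' @slot labels integer array (nz, ny, nx)
#' @slot spacing \linkS4class{VoxelSpacing}
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacing = "VoxelSpacing"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3D array (nz, ny, nx)")
    if (any(object@labels < 0)) return("labels must be nonnegative integers")
    TRUE
  })

#' Medial-axis skeleton of a binary mask
#'
#' One-voxel-wide curve skeleton; nodes are foreground voxels of the source
#' mask, adjacency is 26-connectivity. Branch points have three or more
#' skeleton neighbors, end points exactly one.
#'
#' @slot voxels integer array (nz, ny, nx), 1 on the medial axis
#' @slot spacing \linkS4class{VoxelSpacing}
#' @export
setClass("Skeleton",
  representation(voxels = "array", spacing = "VoxelSpacing"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array (nz, ny, nx)")
    v <- object@voxels
    if (!all(v == 0 | v == 1)) return("skeleton values must be 0 or 1")
    TRUE
  })

#' One centerline vessel segment with its morphometric measures
#'
#' A maximal branch-point-free path of the vascular skeleton. Points are
#' ordered terminal-to-terminal in physical micrometres; per-point radii are
#' distances to the nearest background voxel.
#'
#' @slot points N x 3 matrix of (x, y, z) centerline coordinates (um)
#' @slot radii per-point radius (um)
#' @slot diameter twice the median radius (um)
#' @slot length sum of consecutive point distances (um)
#' @slot tortuosity path length over endpoint chord (>= 1); NA for loops
#' @slot centroid mean of the skeleton coordinates (x, y, z) (um)
#' @slot ivd distance to the nearest other segment centroid (um); NA until
#'   the parent set computes it
#' @export
setClass("VesselSegment",
  representation(points = "matrix", radii = "numeric", diameter = "numeric",
                 length = "numeric", tortuosity = "numeric",
                 centroid = "numeric", ivd = "numeric"),
  validity = function(object) {
    if (nrow(object@points) < 2L) return("a segment needs >= 2 points")
    if (ncol(object@points) != 3L) return("points must be N x 3 (x, y, z)")
    if (length(object@radii) != nrow(object@points))
      return("one radius per centerline point required")
    if (any(object@radii <= 0)) return("radii must be strictly positive")
    if (object@length <= 0) return("segment length must be positive")
    if (!is.na(object@tortuosity) && object@tortuosity < 1 - 1e-9)
      return("tortuosity must be >= 1 for distinct endpoints")
    TRUE
  })

#' All vessel segments of one stack plus volume totals
#'
#' @slot segments list of \linkS4class{VesselSegment}
#' @slot totalVolume total vascular volume, foreground voxel count times
#'   voxel volume (um^3)
#' @slot nVesselVoxels foreground voxel count of the source mask
#' @slot voxelVolume dx*dy*dz (um^3)
#' @slot spacing \linkS4class{VoxelSpacing}
#' @export
setClass("SegmentSet",
  representation(segments = "list", totalVolume = "numeric",
                 nVesselVoxels = "numeric", voxelVolume = "numeric",
                 spacing = "VoxelSpacing"),
  validity = function(object) {
    if (!all(vapply(object@segments, is, logical(1), "VesselSegment")))
      return("segments must all be VesselSegment objects")
    if (abs(object@totalVolume -
            object@nVesselVoxels * object@voxelVolume) > 1e-9 *
        max(1, object@totalVolume))
      return("totalVolume must equal nVesselVoxels * voxelVolume")
    TRUE
  })

#' Per-frame motion assessment report
#'
#' Shifts of the intensity-weighted centroid of tracked single-vessel
#' structures between consecutive planes, in pixels.
#'
#' @slot shifts data.frame with columns plane (index of the deeper plane,
#'   1-based), structure (tracked structure id), shift (pixels)
#' @slot maxShift maximum over all listed shifts (pixels)
#' @export
setClass("MotionReport",
  representation(shifts = "data.frame", maxShift = "numeric"),
  validity = function(object) {
    if (!all(c("plane", "structure", "shift") %in% colnames(object@shifts)))
      return("shifts needs columns plane, structure, shift")
    if (nrow(object@shifts) > 0) {
      if (any(object@shifts$shift < 0)) return("shifts must be nonnegative")
      if (abs(object@maxShift - max(object@shifts$shift)) > 1e-12)
        return("maxShift must equal the maximum listed shift")
    }
    TRUE
  })

#' Ground-truth description of one synthetic vessel
#'
#' @slot centerline M x 3 matrix of (x, y, z) polyline vertices (um)
#' @slot radius constant tube radius (um)
#' @slot intensity peak intensity before depth attenuation
#' @export
setClass("VesselTruth",
  representation(centerline = "matrix", radius = "numeric",
                 intensity = "numeric"),
  validity = function(object) {
    if (nrow(object@centerline) < 2L) return("centerline needs >= 2 points")
    if (ncol(object@centerline) != 3L) return("centerline must be M x 3")
    steps <- diff(object@centerline)
    if (any(rowSums(steps^2) == 0))
      return("consecutive centerline points must be distinct")
    if (object@radius <= 0) return("radius must be positive")
    TRUE
  })

#' Ground-truth description of one synthetic plaque
#'
#' @slot center (x, y, z) sphere center (um)
#' @slot radius sphere radius (um)
#' @slot intensity peak intensity before depth attenuation
#' @export
setClass("PlaqueTruth",
  representation(center = "numeric", radius = "numeric",
                 intensity = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3L) return("center must be (x, y, z)")
    if (object@radius <= 0) return("radius must be positive")
    TRUE
  })

#' Full description of a synthetic two-channel phantom
#'
#' @slot shape integer (nz, ny, nx)
#' @slot spacing \linkS4class{VoxelSpacing}
#' @slot vessels list of \linkS4class{VesselTruth}
#' @slot plaques list of \linkS4class{PlaqueTruth}
#' @slot attenuationLength exponential decay length of signal with depth
#'   (um); Inf disables attenuation
#' @slot backgroundLevel additive background intensity
#' @slot noiseGaussianSD Gaussian read-noise standard deviation (0 = off)
#' @slot noisePoisson whether to draw voxel intensities as Poisson counts
#' @slot crosstalkAlpha fraction of each channel leaking into the other,
#'   in [0, 1)
#' @slot jitter nz x 2 integer matrix of per-plane (dy, dx) pixel shifts
#' @slot seed RNG seed making the rendered stacks reproducible
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "VoxelSpacing",
                 vessels = "list", plaques = "list",
                 attenuationLength = "numeric", backgroundLevel = "numeric",
                 noiseGaussianSD = "numeric", noisePoisson = "logical",
                 crosstalkAlpha = "numeric", jitter = "matrix",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be three positive integers (nz, ny, nx)")
    if (object@crosstalkAlpha < 0 || object@crosstalkAlpha >= 1)
      return("crosstalkAlpha must lie in [0, 1)")
    if (object@attenuationLength <= 0)
      return("attenuationLength must be positive (Inf to disable)")
    if (nrow(object@jitter) != object@shape[1] || ncol(object@jitter) != 2L)
      return("jitter must be an nz x 2 integer matrix of (dy, dx) shifts")
    ext <- physicalExtent(object@shape, object@spacing)
    for (v in object@vessels) {
      if (!is(v, "VesselTruth")) return("vessels must be VesselTruth objects")
      lo <- apply(v@centerline, 2, min) - v@radius
      hi <- apply(v@centerline, 2, max) + v@radius
      if (any(lo < 0) || any(hi > ext))
        return("a vessel tube extends beyond the stack bounds")
    }
    for (p in object@plaques) {
      if (!is(p, "PlaqueTruth")) return("plaques must be PlaqueTruth objects")
      if (any(p@center - p@radius < 0) || any(p@center + p@radius > ext))
        return("a plaque sphere extends beyond the stack bounds")
    }
    TRUE
  })

# physical extent (x, y, z) of a shape = c(nz, ny, nx) grid of voxel centers
physicalExtent <- function(shape, spacing) {
  c((shape[3] - 1L) * spacing@dx,
    (shape[2] - 1L) * spacing@dy,
    (shape[1] - 1L) * spacing@dz)
}
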