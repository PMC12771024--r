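#' @include AllClasses.R
NULL

#' Accessors for stack-like objects
#'
#' \code{voxels} returns the raw 3D array (dim \code{(nz, ny, nx)});
#' \code{spacing} the \linkS4class{VoxelSpacing}; \code{voxelVolume} the
#' physical volume of one voxel in cubic micrometres.
#'
#' @param object an \linkS4class{ImageStack}, \linkS4class{BinaryMask},
#'   \linkS4class{LabelVolume} or \linkS4class{Skeleton}
#' @return array, \linkS4class{VoxelSpacing} or numeric scalar
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setMethod("voxels", "ImageStack", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "BinaryMask", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "Skeleton", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "LabelVolume", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageStack", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "BinaryMask", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "Skeleton", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "LabelVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelVolume", "VoxelSpacing",
          function(object) object@dx * object@dy * object@dz)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "ImageStack",
          function(object) voxelVolume(object@spacing))
#' @rdname accessors
#' @export
setMethod("voxelVolume", "BinaryMask",
          function(object) voxelVolume(object@spacing))
#' @rdname accessors
#' @export
setMethod("voxelVolume", "LabelVolume",
          function(object) voxelVolume(object@spacing))

#' Channel tag of a stack
#'
#' @param object an \linkS4class{ImageStack}
#' @return "vessel", "plaque" or "thg"
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @rdname channelName
#' @export
setMethod("channelName", "ImageStack", function(object) object@channel)

#' Maximum representable intensity of a stack
#'
#' @param object an \linkS4class{ImageStack}
#' @return scalar, e.g. 255 or 65535
#' @export
setGeneric("bitDepthMax", function(object) standardGeneric("bitDepthMax"))

#' @rdname bitDepthMax
#' @export
setMethod("bitDepthMax", "ImageStack", function(object) object@bitDepthMax)

#' Accessors for segment sets
#'
#' @param object a \linkS4class{SegmentSet}
#' @return \code{segments}: list of \linkS4class{VesselSegment};
#'   \code{segmentMetrics}: one data.frame row per segment with diameter,
#'   length, tortuosity, centroid and inter-vessel distance;
#'   \code{totalVolume} and \code{nVesselVoxels}: scalars.
#' @name segment-accessors
NULL

#' @rdname segment-accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname segment-accessors
#' @export
setMethod("segments", "SegmentSet", function(object) object@segments)

#' @rdname segment-accessors
#' @export
setGeneric("segmentMetrics", function(object) standardGeneric("segmentMetrics"))
#' @rdname segment-accessors
#' @export
setMethod("segmentMetrics", "SegmentSet", function(object) {
  segs <- object@segments
  if (length(segs) == 0L) {
    return(data.frame(segment = integer(), diameter = numeric(),
                      length = numeric(), tortuosity = numeric(),
                      ivd = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric()))
  }
  data.frame(
    segment = seq_along(segs),
    diameter = vapply(segs, function(s) s@diameter, numeric(1)),
    length = vapply(segs, function(s) s@length, numeric(1)),
    tortuosity = vapply(segs, function(s) s@tortuosity, numeric(1)),
    ivd = vapply(segs, function(s) s@ivd, numeric(1)),
    centroid_x = vapply(segs, function(s) s@centroid[1], numeric(1)),
    centroid_y = vapply(segs, function(s) s@centroid[2], numeric(1)),
    centroid_z = vapply(segs, function(s) s@centroid[3], numeric(1)))
})

#' @rdname segment-accessors
#' @export
setGeneric("totalVolume", function(object) standardGeneric("totalVolume"))
#' @rdname segment-accessors
#' @export
setMethod("totalVolume", "SegmentSet", function(object) object@totalVolume)

#' @rdname segment-accessors
#' @export
setGeneric("nVesselVoxels", function(object) standardGeneric("nVesselVoxels"))
#' @rdname segment-accessors
#' @export
setMethod("nVesselVoxels", "SegmentSet", function(object) object@nVesselVoxels)

#' Per plane-pair centroid shifts of a motion report
#'
#' @param object a \linkS4class{MotionReport}
#' @return data.frame with columns plane, structure, shift (pixels)
#' @export
setGeneric("motionShifts", function(object) standardGeneric("motionShifts"))
#' @rdname motionShifts
#' @export
setMethod("motionShifts", "MotionReport", function(object) object@shifts)

#' Maximum centroid shift over all plane pairs
#'
#' @param object a \linkS4class{MotionReport}
#' @return shift in pixels
#' @export
setGeneric("maxShift", function(object) standardGeneric("maxShift"))
#' @rdname maxShift
#' @export
setMethod("maxShift", "MotionReport", function(object) object@maxShift)

setMethod("show", "VoxelSpacing", function(object) {
  cat(sprintf("VoxelSpacing: dx=%g dy=%g dz=%g um (voxel volume %g um^3)\n",
              object@dx, object@dy, object@dz, voxelVolume(object)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ImageStack '%s' channel=%s: %d planes of %d x %d (z,y,x), max %g/%g\n",
    object@sessionId, object@channel, d[1], d[2], d[3],
    max(object@voxels), object@bitDepthMax))
  cat("  "); show(object@spacing)
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask: %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "Skeleton", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Skeleton: %d nodes in a %d x %d x %d volume\n",
              sum(object@voxels), d[1], d[2], d[3]))
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %d components\n", max(object@labels)))
})

setMethod("show", "VesselSegment", function(object) {
  cat(sprintf(
    "VesselSegment: %d points, D=%.2f um, L=%.1f um, T=%.3f, IVD=%s\n",
    nrow(object@points), object@diameter, object@length, object@tortuosity,
    ifelse(is.na(object@ivd), "NA", sprintf("%.1f um", object@ivd))))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf(
    "SegmentSet: %d segments, V_vessel=%.1f um^3 (%d voxels x %.4f um^3)\n",
    length(object@segments), object@totalVolume, object@nVesselVoxels,
    object@voxelVolume))
})

setMethod("show", "MotionReport", function(object) {
  cat(sprintf("MotionReport: %d plane-pair shifts, max %.2f px\n",
              nrow(object@shifts), object@maxShift))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d x %d (z,y,x), %d vessels, %d plaques, seed %d\n",
    object@shape[1], object@shape[2], object@shape[3],
    length(object@vessels), length(object@plaques), object@seed))
})
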