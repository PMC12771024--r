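#' @include AllClasses.R utils.R
NULL

#' Segment amyloid plaques
#'
#' Semi-automatic mode reproduces the multilevel-Otsu workflow: four
#' intensity thresholds are computed over the whole volume (five classes)
#' and voxels in the two highest classes (intensity at or above the third
#' threshold) form the binary plaque image; per plane, small holes are
#' filled and objects smaller than \code{minObjectPx} pixels removed; the
#' cleaned binary volume is then labeled by 3D connected components
#' (26-connectivity). Manual mode labels an externally edited mask directly,
#' supporting the manual-annotation workflow used when plaque load or image
#' quality makes thresholding unreliable (the reference workflow switched to
#' semi-automatic segmentation only above 45 well-imaged plaques).
#'
#' @param stack plaque-channel \linkS4class{ImageStack} (semi_auto mode)
#' @param mode \code{"semi_auto"} or \code{"manual_mask"}
#' @param manual \linkS4class{BinaryMask} for manual mode
#' @param minObjectPx smallest in-plane object kept before labeling
#' @return a \linkS4class{LabelVolume}; 0 labels with a warning when nothing
#'   is found
#' @export
segmentPlaques <- function(stack, mode = c("semi_auto", "manual_mask"),
                           manual = NULL, minObjectPx = 5L) {
  mode <- match.arg(mode)
  if (mode == "manual_mask") {
    if (is.null(manual)) stop("manual_mask mode requires a mask")
    lab <- array(.label3d(voxels(manual), dim(voxels(manual)), 26L),
                 dim = dim(voxels(manual)))
    if (max(lab) == 0L) warning("manual mask is empty: 0 plaque labels")
    return(new("LabelVolume", labels = lab, spacing = spacing(manual)))
  }
  v <- voxels(stack)
  if (min(v) == max(v)) stop("cannot threshold a constant stack")
  thr <- otsuThresholds(v, 4L)
  bin <- array(as.integer(v >= thr[3]), dim = dim(v))
  for (z in seq_len(dim(v)[1])) {
    plane <- EBImage::Image(t(bin[z, , ]))
    plane <- EBImage::fillHull(plane)
    if (minObjectPx > 0L) {
      lab2d <- EBImage::bwlabel(plane)
      cnt <- tabulate(as.integer(EBImage::imageData(lab2d)))
      drop <- which(cnt < minObjectPx)
      if (length(drop))
        lab2d <- EBImage::rmObjects(lab2d, drop, reenumerate = FALSE)
      plane <- lab2d > 0
    }
    bin[z, , ] <- t(EBImage::imageData(plane) != 0)
  }
  lab <- array(.label3d(bin, dim(bin), 26L), dim = dim(bin))
  if (max(lab) == 0L) warning("no plaque regions found")
  new("LabelVolume", labels = lab, spacing = spacing(stack))
}

# per-label, per-plane pixel counts: data.frame(label, z, pixels)
.slicePixelCounts <- function(labels) {
  lab <- voxels(labels)
  nz <- dim(lab)[1]
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    plane <- lab[z, , ]
    plane <- plane[plane > 0]
    if (!length(plane)) next
    tt <- table(plane)
    out[[z]] <- data.frame(label = as.integer(names(tt)), z = z,
                           pixels = as.integer(tt))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(label = integer(), z = integer(), pixels = integer())
  res
}

#' Per-slice cross-sectional areas of labeled plaques
#'
#' @param labels a \linkS4class{LabelVolume}
#' @return data.frame with columns label, z (1-based plane), area (um^2,
#'   pixel count times dx*dy)
#' @export
plaqueSliceAreas <- function(labels) {
  sp <- spacing(labels)
  df <- .slicePixelCounts(labels)
  df$area <- df$pixels * sp@dx * sp@dy
  df[, c("label", "z", "area")]
}

#' Remove plaque components by cross-sectional area
#'
#' A 3D component is excluded when its area falls strictly below
#' \code{minArea} (default 49 um^2). With \code{mode = "max_slice"} (the
#' default) the tested area is the component's largest single-plane
#' cross-section, keeping the criterion's units literal; \code{"total"}
#' instead tests the summed area over all planes. Surviving labels are
#' re-indexed contiguously from 1 in their original order; the operation is
#' idempotent.
#'
#' @param labels a \linkS4class{LabelVolume}
#' @param minArea exclusion threshold (um^2)
#' @param mode \code{"max_slice"} or \code{"total"}
#' @return filtered \linkS4class{LabelVolume}
#' @export
filterSmallRegions <- function(labels, minArea = 49,
                               mode = c("max_slice", "total")) {
  mode <- match.arg(mode)
  sa <- plaqueSliceAreas(labels)
  if (!nrow(sa)) return(labels)
  areaPerLabel <- if (mode == "max_slice") {
    tapply(sa$area, sa$label, max)
  } else {
    tapply(sa$area, sa$label, sum)
  }
  keep <- as.integer(names(areaPerLabel))[areaPerLabel >= minArea]
  lab <- voxels(labels)
  newIds <- integer(max(lab))
  newIds[sort(keep)] <- seq_along(keep)
  out <- array(0L, dim = dim(lab))
  sel <- lab > 0L
  out[sel] <- newIds[lab[sel]]
  new("LabelVolume", labels = out, spacing = spacing(labels))
}

#' Plaque volumes from per-slice areas
#'
#' Volume of each labeled plaque: summed per-slice areas times the axial
#' step, \code{sum(pixels) * dx * dy * dz}.
#'
#' @param labels a \linkS4class{LabelVolume}
#' @return named numeric vector of volumes (um^3), one per label
#' @export
plaqueVolumes <- function(labels) {
  sp <- spacing(labels)
  sa <- .slicePixelCounts(labels)
  if (!nrow(sa)) stop("no labeled regions")
  v <- tapply(sa$pixels, sa$label, sum) * sp@dx * sp@dy * sp@dz
  stats::setNames(as.numeric(v), names(v))
}

#' Equivalent-sphere radius from a measured volume
#'
#' \code{r = (3 V / (4 pi))^(1/3)}, the radius of the sphere with the same
#' volume; reported for comparability across irregular plaques.
#'
#' @param volume volume(s) in um^3, strictly positive
#' @return radius (um), vectorized
#' @examples
#' plaqueRadius(4 * pi / 3)   # 1
#' @export
plaqueRadius <- function(volume) {
  if (any(volume <= 0)) stop("volume must be strictly positive")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Nearest vessel distance from plaque centroids
#'
#' Minimum physical Euclidean distance from each plaque centroid to any
#' vessel foreground voxel center.
#'
#' @param centroids K x 3 matrix of plaque centroids (x, y, z) in um
#' @param vesselMask a non-empty \linkS4class{BinaryMask}
#' @return numeric vector of distances (um)
#' @export
nearestPlaqueVesselDistance <- function(centroids, vesselMask) {
  m <- voxels(vesselMask)
  if (!any(m == 1L)) stop("vessel mask is empty")
  sp <- spacing(vesselMask)
  centroids <- matrix(as.numeric(centroids), ncol = 3L)
  .minDistToForeground(centroids, m, dim(m), sp@dz, sp@dy, sp@dx)
}

#' Full plaque morphometry table
#'
#' Per labeled region: per-slice-summed volume, equivalent-sphere radius,
#' unweighted physical centroid, largest single-plane area, and (when a
#' vessel mask is supplied) the nearest-vessel distance of the centroid.
#'
#' @param labels a \linkS4class{LabelVolume} (normally already filtered with
#'   \code{\link{filterSmallRegions}})
#' @param vesselMask optional \linkS4class{BinaryMask}
#' @return data.frame with one row per label
#' @export
plaqueMorphometry <- function(labels, vesselMask = NULL) {
  lab <- voxels(labels)
  sp <- spacing(labels)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(label = integer(), volume = numeric(),
                      equivalentRadius = numeric(), maxSliceArea = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(),
                      nearestVesselDistance = numeric()))
  vols <- plaqueVolumes(labels)
  sa <- plaqueSliceAreas(labels)
  maxArea <- tapply(sa$area, sa$label, max)
  idx <- which(lab > 0L)
  coord <- arrayInd(idx, dim(lab))
  phys <- .voxelToPhysical(coord, sp)
  lv <- lab[idx]
  ctr <- cbind(tapply(phys[, 1], lv, mean), tapply(phys[, 2], lv, mean),
               tapply(phys[, 3], lv, mean))
  df <- data.frame(label = seq_len(k),
                   volume = as.numeric(vols[as.character(seq_len(k))]),
                   equivalentRadius = plaqueRadius(
                     as.numeric(vols[as.character(seq_len(k))])),
                   maxSliceArea = as.numeric(maxArea[as.character(seq_len(k))]),
                   centroid_x = ctr[as.character(seq_len(k)), 1],
                   centroid_y = ctr[as.character(seq_len(k)), 2],
                   centroid_z = ctr[as.character(seq_len(k)), 3])
  df$nearestVesselDistance <- if (!is.null(vesselMask)) {
    nearestPlaqueVesselDistance(
      as.matrix(df[, c("centroid_x", "centroid_y", "centroid_z")]),
      vesselMask)
  } else NA_real_
  rownames(df) <- NULL
  df
}
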