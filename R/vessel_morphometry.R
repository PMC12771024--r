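#' @include AllClasses.R utils.R
NULL

#' Dice similarity coefficient between two binary masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; the standard overlap QC between an
#' automated segmentation and a manual annotation. Values below
#' \code{threshold} (default 0.70) are flagged for manual correction, the QC
#' rule applied to the reference segmentations.
#'
#' @param pred predicted \linkS4class{BinaryMask}
#' @param truth reference \linkS4class{BinaryMask}, same shape
#' @param threshold QC cutoff
#' @return the Dice coefficient, with attribute \code{"flag"} set to
#'   \code{"manual correction recommended"} when below threshold (NULL
#'   otherwise)
#' @examples
#' m <- binaryMask(array(c(1, 1, 0, 0), c(1, 2, 2)))
#' diceCoefficient(m, m)   # 1, no flag
#' @export
diceCoefficient <- function(pred, truth, threshold = 0.70) {
  p <- voxels(pred); t <- voxels(truth)
  .checkSameShape(p, t, "masks")
  sp <- sum(p); st <- sum(t)
  if (sp + st == 0) stop("Dice undefined: both masks are empty")
  d <- 2 * sum(p & t) / (sp + st)
  if (d < threshold) attr(d, "flag") <- "manual correction recommended"
  d
}

#' Baseline vessel segmentation by global Otsu thresholding
#'
#' A classical stand-in segmenter for externally produced masks (e.g. from a
#' dedicated vessel-segmentation CNN, which can be imported with
#' \code{\link{readMask}} instead): one global Otsu threshold over the whole
#' volume, followed by removal of 3D components (26-connectivity) smaller
#' than \code{minComponentVoxels}.
#'
#' Vessels occupy only a few percent of cortical volume, so when the single
#' Otsu threshold marks more than \code{maxForegroundFraction} of all voxels
#' the split has fallen inside the background distribution (typical for
#' noisy stacks whose zero-clipped background is bimodal); the segmenter
#' then escalates to a two-threshold (three-class) Otsu and keeps the top
#' class.
#'
#' @param stack an \linkS4class{ImageStack}; must not be constant
#' @param method only \code{"otsu3d"}
#' @param invert set TRUE when vessels are dark on a bright background
#' @param minComponentVoxels smallest retained component (0 keeps all)
#' @param maxForegroundFraction plausibility bound on the vascular volume
#'   fraction triggering the three-class fallback
#' @return a \linkS4class{BinaryMask}
#' @export
baselineSegment <- function(stack, method = "otsu3d", invert = FALSE,
                            minComponentVoxels = 27L,
                            maxForegroundFraction = 0.10) {
  method <- match.arg(method, "otsu3d")
  v <- voxels(stack)
  if (min(v) == max(v)) stop("cannot segment a constant stack")
  work <- if (invert) max(v) - v else v
  thr <- otsuThresholds(work, 1L)
  if (mean(work >= thr) > maxForegroundFraction)
    thr <- otsuThresholds(work, 2L)[2]
  m <- array(as.integer(work >= thr), dim = dim(v))
  if (minComponentVoxels > 0L && any(m == 1L)) {
    lab <- .label3d(m, dim(m), 26L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= minComponentVoxels)
    m <- array(as.integer(lab %in% keep & lab > 0L), dim = dim(v))
  }
  if (!any(m == 1L)) warning("baseline segmentation produced an empty mask")
  binaryMask(m, spacing = spacing(stack))
}

#' Skeletonize a binary mask to a medial-axis curve
#'
#' Topology-preserving iterative thinning: border voxels that are simple
#' points for the (26, 6) foreground/background adjacency pair are peeled in
#' six directional sub-iterations until stable, keeping curve end points.
#' The result is a one-voxel-wide centerline whose connectivity matches the
#' source mask's components.
#'
#' Curve thinning degenerates on voxel grids much coarser along z than in
#' plane (a vessel one voxel thick in z has no stable medial curve), so for
#' anisotropic spacing the mask is first resampled to a near-isotropic grid
#' by plane replication, thinned there, mapped back to the original grid and
#' thinned once more to remove mapping duplicates -- the standard
#' make-isotropic-then-skeletonize practice.
#'
#' @param mask a non-empty \linkS4class{BinaryMask}
#' @return a \linkS4class{Skeleton} on the mask's own grid
#' @export
skeletonize <- function(mask) {
  m <- voxels(mask)
  if (!any(m == 1L)) stop("cannot skeletonize an empty mask")
  sp <- spacing(mask)
  f <- max(1L, as.integer(round(sp@dz / max(sp@dx, sp@dy))))
  if (f > 1L) {
    up <- m[rep(seq_len(dim(m)[1]), each = f), , , drop = FALSE]
    skUp <- array(.thin3d(up, dim(up)), dim = dim(up))
    idx <- which(skUp == 1L, arr.ind = TRUE)
    idx[, 1] <- (idx[, 1] - 1L) %/% f + 1L
    sk <- array(0L, dim = dim(m))
    sk[idx] <- 1L
    sk <- array(.thin3d(sk, dim(sk)), dim = dim(m))
  } else {
    sk <- array(.thin3d(m, dim(m)), dim = dim(m))
  }
  new("Skeleton", voxels = sk, spacing = sp)
}

# adjacency of skeleton nodes: list mapping node id -> integer neighbor ids
.skeletonGraph <- function(skel) {
  sk <- voxels(skel)
  dims <- dim(sk)
  idx <- which(sk == 1L)
  coord <- arrayInd(idx, dims)        # columns z, y, x
  id <- integer(prod(dims))
  id[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbrs <- vector("list", length(idx))
  for (i in seq_along(idx)) nbrs[[i]] <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nz <- coord[, 1] + offs[k, 1]
    ny <- coord[, 2] + offs[k, 2]
    nx <- coord[, 3] + offs[k, 3]
    ok <- nz >= 1 & nz <= dims[1] & ny >= 1 & ny <= dims[2] &
          nx >= 1 & nx <= dims[3]
    if (!any(ok)) next
    nid <- id[.linIndex(nz[ok], ny[ok], nx[ok], dims)]
    src <- which(ok)[nid > 0]
    nid <- nid[nid > 0]
    for (j in seq_along(src))
      nbrs[[src[j]]] <- c(nbrs[[src[j]]], nid[j])
  }
  list(coord = coord, nbrs = nbrs)
}

#' Split a skeleton into branch-free vessel segments
#'
#' Segments are maximal paths between terminals (end points with one
#' neighbor, branch points with three or more); every non-branch skeleton
#' voxel belongs to exactly one segment. Paths shorter than \code{minNodes}
#' nodes are discarded as skeletonization spurs. Isolated cycles (no
#' terminal) are returned as a single closed path.
#'
#' @param skel a \linkS4class{Skeleton}
#' @param minNodes minimum node count for a retained segment
#' @return list of integer matrices, each N x 3 with columns (z, y, x) of
#'   ordered 1-based voxel indices
#' @export
splitSegments <- function(skel, minNodes = 3L) {
  g <- .skeletonGraph(skel)
  nbrs <- g$nbrs
  n <- length(nbrs)
  if (n == 0L) stop("empty skeleton")
  deg <- lengths(nbrs)
  terminal <- deg != 2L
  edgeKey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  paths <- list()
  walk <- function(start, second) {
    path <- c(start, second)
    prev <- start; cur <- second
    while (!terminal[cur]) {
      nxt <- setdiff(nbrs[[cur]], prev)
      if (length(nxt) == 0L) break
      nxt <- nxt[1]
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (cur == start) break   # closed loop
    }
    path
  }
  for (t in which(terminal)) {
    for (s in nbrs[[t]]) {
      ek <- edgeKey(t, s)
      if (!is.null(visited[[ek]])) next
      path <- walk(t, s)
      for (i in seq_len(length(path) - 1L))
        assign(edgeKey(path[i], path[i + 1L]), TRUE, envir = visited)
      paths[[length(paths) + 1L]] <- path
    }
  }
  # cycles without terminals
  inPath <- rep(FALSE, n)
  for (p in paths) inPath[p] <- TRUE
  for (s in which(!inPath & deg == 2L)) {
    if (inPath[s]) next
    path <- walk(s, nbrs[[s]][1])
    inPath[path] <- TRUE
    paths[[length(paths) + 1L]] <- path
  }
  paths <- Filter(function(p) length(p) >= minNodes, paths)
  lapply(paths, function(p) g$coord[p, , drop = FALSE])
}

#' Per-point centerline radius from the distance to background
#'
#' The radius at each centerline voxel is its minimum Euclidean distance to
#' any background voxel, measured in physical micrometres so the anisotropic
#' axial spacing is respected. Computed with an exact separable distance
#' transform.
#'
#' @param path N x 3 integer matrix of (z, y, x) voxel indices (1-based),
#'   all foreground in \code{mask}
#' @param mask the source \linkS4class{BinaryMask}
#' @return numeric vector of radii (um)
#' @export
vesselRadiusProfile <- function(path, mask) {
  m <- voxels(mask)
  if (all(m == 1L)) stop("mask has no background voxels")
  sp <- spacing(mask)
  edt <- .edt3d(m, dim(m), sp@dz, sp@dy, sp@dx)
  if (any(m[.linIndex(path[, 1], path[, 2], path[, 3], dim(m))] == 0L))
    stop("path contains background voxels")
  edt[.linIndex(path[, 1], path[, 2], path[, 3], dim(m))]
}

#' Vessel diameter: twice the median centerline radius
#'
#' Even-count medians average the two central values.
#'
#' @param radii per-point radii (um), non-empty
#' @return diameter (um)
#' @examples
#' vesselDiameter(c(1, 2, 3, 4))   # 5
#' @export
vesselDiameter <- function(radii) {
  if (!length(radii)) stop("empty radius profile")
  2 * stats::median(radii)
}

#' Vessel length: sum of consecutive centerline point distances
#'
#' @param points N x 3 matrix of ordered (x, y, z) coordinates in um, N >= 2
#' @return path length (um)
#' @export
vesselLength <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("length needs at least 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Vessel tortuosity: path length over endpoint chord
#'
#' Equals 1 for a straight segment; undefined (error) when the endpoints
#' coincide (closed loop).
#'
#' @param points N x 3 matrix of ordered (x, y, z) coordinates in um
#' @return tortuosity (dimensionless, >= 1)
#' @export
vesselTortuosity <- function(points) {
  points <- as.matrix(points)
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (chord == 0) stop("undefined tortuosity: endpoints coincide")
  vesselLength(points) / chord
}

#' Total vascular volume of a mask
#'
#' Foreground voxel count times the physical voxel volume; exact by
#' construction.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @return volume in um^3, with attribute \code{"nVoxels"}
#' @export
totalVesselVolume <- function(mask) {
  n <- sum(voxels(mask))
  v <- n * voxelVolume(mask)
  attr(v, "nVoxels") <- n
  v
}

#' Inter-vessel distance per segment
#'
#' Each segment is reduced to its skeleton centroid; the IVD of a segment is
#' the minimum Euclidean distance from its centroid to any other segment's
#' centroid, in physical micrometres.
#'
#' @param centroids K x 3 matrix of segment centroids (x, y, z) in um, or a
#'   \linkS4class{SegmentSet}
#' @return numeric vector of per-segment IVDs
#' @export
interVesselDistance <- function(centroids) {
  if (is(centroids, "SegmentSet"))
    centroids <- do.call(rbind, lapply(segments(centroids),
                                       function(s) s@centroid))
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 2L) stop("inter-vessel distance needs at least 2 segments")
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

# moving-average smoothing of an ordered centerline; endpoints stay fixed.
# Counteracts the voxel staircase, which otherwise inflates path length (and
# hence tortuosity) of oblique segments.
.smoothPath <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n < 3L || window < 2L) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in 2L:(n - 1L)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

#' Full vascular morphometry of a binary mask
#'
#' Skeletonizes the mask, splits the skeleton into branch-free segments, and
#' computes per-segment diameter (twice the median centerline radius,
#' radius = physical distance to the nearest background voxel), length,
#' tortuosity (NA for closed loops), centroid and inter-vessel distance,
#' plus the total vascular volume.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @param minNodes spur-pruning threshold passed to
#'   \code{\link{splitSegments}}
#' @param smoothWindow moving-average window (in centerline nodes) applied
#'   to the voxel centerline before measuring length and tortuosity;
#'   counteracts staircase inflation on oblique vessels. 0 or 1 disables.
#' @param minSegmentLength segments shorter than this (um) are discarded as
#'   skeletonization spurs; default one axial step
#' @return a \linkS4class{SegmentSet}
#' @export
vesselMorphometry <- function(mask, minNodes = 3L, smoothWindow = 5L,
                              minSegmentLength = 5) {
  sp <- spacing(mask)
  m <- voxels(mask)
  skel <- skeletonize(mask)
  paths <- splitSegments(skel, minNodes = minNodes)
  edt <- .edt3d(m, dim(m), sp@dz, sp@dy, sp@dx)
  segs <- lapply(paths, function(p) {
    pts <- .smoothPath(.voxelToPhysical(p, sp), smoothWindow)
    radii <- edt[.linIndex(p[, 1], p[, 2], p[, 3], dim(m))]
    radii <- pmax(radii, .Machine$double.eps)
    tort <- tryCatch(vesselTortuosity(pts), error = function(e) NA_real_)
    new("VesselSegment", points = pts, radii = radii,
        diameter = vesselDiameter(radii), length = vesselLength(pts),
        tortuosity = tort, centroid = colMeans(pts), ivd = NA_real_)
  })
  segs <- Filter(function(s) s@length >= minSegmentLength, segs)
  if (length(segs) >= 2L) {
    ivd <- interVesselDistance(do.call(rbind, lapply(segs,
                                                     function(s) s@centroid)))
    for (i in seq_along(segs)) segs[[i]]@ivd <- ivd[i]
  }
  vol <- totalVesselVolume(mask)
  new("SegmentSet", segments = segs, totalVolume = as.numeric(vol),
      nVesselVoxels = attr(vol, "nVoxels"), voxelVolume = voxelVolume(mask),
      spacing = sp)
}
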