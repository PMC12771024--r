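#' @include AllClasses.R utils.R
NULL

#' Contrast-limited adaptive histogram equalization, per plane
#'
#' Each plane is equalized independently with CLAHE (tiles of the plane are
#' equalized against their local histogram, clipped at \code{clipLimit} of
#' the tile's pixel count to bound noise amplification) and rescaled to
#' [0, bitDepthMax]. All-constant planes pass through unchanged.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param clipLimit relative clip limit in (0, 1]; fraction of the tile's
#'   pixels any histogram bin may hold before redistribution
#' @param tileGrid tiles per axis, length-2 (ty, tx) or a scalar
#' @return equalized \linkS4class{ImageStack}, same shape
#' @export
adaptiveHistEq <- function(stack, clipLimit = 0.01, tileGrid = c(8L, 8L)) {
  stopifnot(clipLimit > 0, clipLimit <= 1)
  if (length(tileGrid) == 1L) tileGrid <- rep(tileGrid, 2L)
  v <- voxels(stack)
  bdm <- bitDepthMax(stack)
  bins <- 256L
  out <- v
  for (z in seq_len(dim(v)[1])) {
    plane <- v[z, , ]
    rng <- range(plane)
    if (rng[1] == rng[2]) next      # degenerate plane: unchanged
    # EBImage expects (x, y); pad to a tile multiple, equalize, crop back
    img <- t(plane) / bdm
    d <- dim(img)
    padTo <- ceiling(d / rev(tileGrid)) * rev(tileGrid)
    padded <- matrix(0, padTo[1], padTo[2])
    padded[seq_len(d[1]), seq_len(d[2])] <- img
    if (padTo[1] > d[1])
      padded[(d[1] + 1):padTo[1], seq_len(d[2])] <-
        img[d[1] - (seq_len(padTo[1] - d[1]) - 1L), , drop = FALSE]
    if (padTo[2] > d[2])
      padded[, (d[2] + 1):padTo[2]] <-
        padded[, d[2] - (seq_len(padTo[2] - d[2]) - 1L), drop = FALSE]
    eq <- EBImage::clahe(EBImage::Image(padded), nx = tileGrid[2],
                         ny = tileGrid[1], bins = bins,
                         limit = clipLimit * bins)
    eqm <- EBImage::imageData(eq)[seq_len(d[1]), seq_len(d[2])]
    eqm <- pmin(pmax(eqm, 0), 1)
    out[z, , ] <- t(eqm) * bdm
  }
  imageStack(out, spacing = spacing(stack), channel = channelName(stack),
             sessionId = stack@sessionId, bitDepthMax = bdm)
}

#' Remove spectral crosstalk by clamped linear unmixing
#'
#' Subtracts a scaled copy of the source channel from the target channel,
#' clamped at zero: \code{corrected = max(target - alpha * source, 0)}. With
#' \code{alpha = "auto"} the coefficient is estimated as the least-squares
#' slope of target on source over voxels where the source exceeds its 99th
#' percentile (bright-source voxels carry the cleanest mixing signature).
#'
#' @param target the contaminated \linkS4class{ImageStack}
#' @param source the contaminating \linkS4class{ImageStack}, same shape
#' @param alpha mixing fraction in [0, 1), or "auto"
#' @return corrected \linkS4class{ImageStack}; the applied (possibly
#'   estimated) coefficient is attached as \code{attr(result, "alpha")}
#' @export
removeCrosstalk <- function(target, source, alpha = "auto") {
  tv <- voxels(target); sv <- voxels(source)
  .checkSameShape(tv, sv, "target and source stacks")
  if (identical(alpha, "auto")) {
    q99 <- stats::quantile(sv, 0.99, names = FALSE)
    sel <- sv >= q99
    if (sum(sel) < 2L) stop("too few bright source voxels to estimate alpha")
    x <- sv[sel]; y <- tv[sel]
    if (stats::var(x) == 0)
      stop("bright source voxels are constant; cannot estimate alpha")
    alpha <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    alpha <- min(max(alpha, 0), 1 - 1e-9)
  }
  stopifnot(is.numeric(alpha), alpha >= 0, alpha < 1)
  corrected <- pmax(tv - alpha * sv, 0)
  res <- imageStack(corrected, spacing = spacing(target),
                    channel = channelName(target),
                    sessionId = target@sessionId,
                    bitDepthMax = bitDepthMax(target))
  attr(res, "alpha") <- alpha
  res
}

#' Remove superficial dura planes
#'
#' Discards the shallowest planes above a boundary. The boundary is either
#' given directly (number of planes to drop, i.e. the 0-based index of the
#' first retained plane) or located from a third-harmonic-generation (THG)
#' stack, whose signal is strong at the dura: within the top 20 percent of
#' planes, the deepest plane whose mean THG intensity exceeds the global THG
#' mean plus two standard deviations marks the dura, and the boundary is
#' that plane plus one.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param boundary integer >= 0, or \code{"from-thg"}
#' @param thg THG \linkS4class{ImageStack}, required for \code{"from-thg"}
#' @return trimmed \linkS4class{ImageStack}; attribute \code{"boundary"}
#'   records the number of planes removed
#' @export
removeDura <- function(stack, boundary = "from-thg", thg = NULL) {
  nz <- dim(voxels(stack))[1]
  if (identical(boundary, "from-thg")) {
    if (is.null(thg)) stop("'from-thg' requires a THG stack")
    tv <- voxels(thg)
    nTop <- max(1L, ceiling(0.2 * dim(tv)[1]))
    planeMeans <- vapply(seq_len(nTop), function(z) mean(tv[z, , ]),
                         numeric(1))
    thr <- mean(tv) + 2 * stats::sd(tv)
    hit <- which(planeMeans > thr)
    boundary <- if (length(hit)) max(hit) else 0L   # planes above dura + dura
  }
  boundary <- as.integer(boundary)
  if (boundary >= nz) stop("boundary (", boundary,
                           ") must be smaller than the plane count ", nz)
  out <- voxels(stack)[(boundary + 1L):nz, , , drop = FALSE]
  res <- imageStack(out, spacing = spacing(stack),
                    channel = channelName(stack),
                    sessionId = stack@sessionId,
                    bitDepthMax = bitDepthMax(stack))
  attr(res, "boundary") <- boundary
  res
}

#' Normalize per-plane intensity against the last non-overexposed plane
#'
#' The reference is the deepest plane whose maximum stays at or below
#' \code{saturationFraction} of the bit-depth maximum (no plane qualifying:
#' the deepest plane). Every other plane is linearly rescaled so its
#' [min, max] range maps onto the reference plane's range, compensating the
#' depth-dependent brightness decay. Constant planes pass through unchanged;
#' a constant reference plane disables scaling with a warning.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param saturationFraction overexposure cutoff, default 0.95
#' @return normalized \linkS4class{ImageStack}; attribute
#'   \code{"referencePlane"} records the 1-based reference index
#' @export
normalizeStack <- function(stack, saturationFraction = 0.95) {
  v <- voxels(stack)
  bdm <- bitDepthMax(stack)
  nz <- dim(v)[1]
  maxes <- vapply(seq_len(nz), function(z) max(v[z, , ]), numeric(1))
  mins <- vapply(seq_len(nz), function(z) min(v[z, , ]), numeric(1))
  # constant planes carry no intensity range and cannot serve as reference
  ok <- which(maxes <= saturationFraction * bdm & maxes > mins)
  ref <- if (length(ok)) max(ok) else nz
  refPlane <- v[ref, , ]
  rlo <- min(refPlane); rhi <- max(refPlane)
  if (rhi == rlo) {
    warning("reference plane ", ref, " is constant; stack left unscaled")
    res <- stack
    attr(res, "referencePlane") <- ref
    return(res)
  }
  out <- v
  for (z in seq_len(nz)) {
    plane <- v[z, , ]
    lo <- min(plane); hi <- max(plane)
    if (hi == lo) next
    out[z, , ] <- (plane - lo) / (hi - lo) * (rhi - rlo) + rlo
  }
  res <- imageStack(pmin(pmax(out, 0), bdm), spacing = spacing(stack),
                    channel = channelName(stack),
                    sessionId = stack@sessionId, bitDepthMax = bdm)
  attr(res, "referencePlane") <- ref
  res
}

#' Denoise a stack with a 3D median filter
#'
#' Median over a box neighborhood clipped at the volume boundary;
#' edge-preserving, deterministic. \code{radius} is interpreted in in-plane
#' voxels and converted to a physical size per axis: on a grid sampled much
#' more coarsely along z than in plane the axial radius shrinks accordingly
#' (to 0 planes at 5 um steps with sub-micrometre pixels), so the filter
#' cannot erase vessels that are only one plane thick.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param method only \code{"median3d"}
#' @param radius in-plane neighborhood radius in voxels (>= 1)
#' @return denoised \linkS4class{ImageStack}
#' @export
denoiseStack <- function(stack, method = "median3d", radius = 1L) {
  method <- match.arg(method, "median3d")
  stopifnot(radius >= 1)
  sp <- spacing(stack)
  rz <- as.integer(round(radius * max(sp@dx, sp@dy) / sp@dz))
  v <- voxels(stack)
  out <- array(.medianFilter3d(as.numeric(v), dim(v), rz,
                               as.integer(radius), as.integer(radius)),
               dim = dim(v))
  imageStack(out, spacing = spacing(stack), channel = channelName(stack),
             sessionId = stack@sessionId, bitDepthMax = bitDepthMax(stack))
}

#' Assess per-frame motion from tracked vascular structures
#'
#' Binarizes each plane (per-plane Otsu threshold by default), tracks up to
#' \code{nStructures} single-vessel structures across consecutive planes by
#' largest voxel overlap, and reports the shift of each structure's
#' intensity-weighted centroid between consecutive planes, in pixels. The
#' maximum shift summarizes whether motion correction would be warranted;
#' the reference pipeline found at most 2 pixels and applied none.
#'
#' @param stack an \linkS4class{ImageStack} (raw data, pre-denoising)
#' @param nStructures maximum number of structures to track
#' @param threshold \code{"otsu"} or a fixed intensity
#' @return a \linkS4class{MotionReport}
#' @export
assessMotion <- function(stack, nStructures = 5L, threshold = "otsu") {
  v <- voxels(stack)
  nz <- dim(v)[1]
  if (nz < 2L) stop("motion assessment needs at least 2 planes")
  binPlanes <- vector("list", nz)
  labPlanes <- vector("list", nz)
  for (z in seq_len(nz)) {
    plane <- v[z, , ]
    thr <- if (identical(threshold, "otsu")) {
      if (min(plane) == max(plane)) Inf else otsuThresholds(plane, 1L)
    } else threshold
    bin <- plane >= thr
    binPlanes[[z]] <- bin
    labPlanes[[z]] <-
      EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bin))))
  }
  fgPlanes <- which(vapply(binPlanes, any, logical(1)))
  if (!length(fgPlanes)) stop("no foreground structure found")

  wCentroid <- function(z, sel) {
    # sel: logical (y, x); weights from raw intensities
    w <- v[z, , ][sel]
    idx <- which(sel, arr.ind = TRUE)
    c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  }

  seedPlanes <- unique(round(seq(min(fgPlanes), max(fgPlanes),
                                 length.out = min(nStructures,
                                                  length(fgPlanes)))))
  used <- matrix(FALSE, 0L, 2L)  # (plane, label) pairs already tracked
  rows <- list()
  sid <- 0L
  for (sz in seedPlanes) {
    if (!any(binPlanes[[sz]])) next
    lab <- labPlanes[[sz]]
    sizes <- table(lab[lab > 0])
    for (cand in as.integer(names(sort(sizes, decreasing = TRUE)))) {
      if (!any(used[, 1] == sz & used[, 2] == cand)) {
        sid <- sid + 1L
        used <- rbind(used, c(sz, cand))
        # track forward from (sz, cand)
        curSel <- t(lab == cand)
        prevCentroid <- wCentroid(sz, curSel)
        z <- sz
        while (z < nz) {
          nxtLab <- labPlanes[[z + 1L]]
          overlap <- t(nxtLab)[curSel]
          overlap <- overlap[overlap > 0]
          if (!length(overlap)) break
          nxt <- as.integer(names(which.max(table(overlap))))
          nxtSel <- t(nxtLab == nxt)
          ctr <- wCentroid(z + 1L, nxtSel)
          rows[[length(rows) + 1L]] <-
            data.frame(plane = z + 1L, structure = sid,
                       shift = sqrt(sum((ctr - prevCentroid)^2)))
          used <- rbind(used, c(z + 1L, nxt))
          prevCentroid <- ctr
          curSel <- nxtSel
          z <- z + 1L
        }
        break
      }
    }
    if (sid >= nStructures) break
  }
  shifts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plane = integer(), structure = integer(), shift = numeric())
  new("MotionReport", shifts = shifts,
      maxShift = if (nrow(shifts)) max(shifts$shift) else 0)
}

#' Run the full preprocessing chain in its fixed order
#'
#' Equalize, crosstalk-correct, dura-remove, normalize, denoise -- the order
#' is fixed; individual steps can be disabled.
#'
#' @param stack the channel to process
#' @param other the other channel (crosstalk source); NULL skips unmixing
#' @param thg optional THG stack for dura detection; NULL with
#'   \code{duraBoundary = 0} skips dura removal
#' @param duraBoundary planes to drop, or \code{"from-thg"}
#' @param config settings list from \code{\link{defaultConfig}}
#' @param equalize,normalize,denoise logical switches for those steps
#' @return processed \linkS4class{ImageStack}
#' @export
preprocessStack <- function(stack, other = NULL, thg = NULL,
                            duraBoundary = 0L, config = defaultConfig(),
                            equalize = TRUE, normalize = TRUE,
                            denoise = TRUE) {
  out <- stack
  if (equalize)
    out <- adaptiveHistEq(out, clipLimit = config$clip_limit,
                          tileGrid = config$tile_grid)
  if (!is.null(other))
    out <- removeCrosstalk(out, other, alpha = config$crosstalk_alpha)
  if (identical(duraBoundary, "from-thg") ||
      (is.numeric(duraBoundary) && duraBoundary > 0))
    out <- removeDura(out, boundary = duraBoundary, thg = thg)
  if (normalize)
    out <- normalizeStack(out, saturationFraction = config$saturation_fraction)
  if (denoise)
    out <- denoiseStack(out, radius = config$median_radius)
  out
}
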