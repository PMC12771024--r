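#' @include AllClasses.R utils.R
NULL

#' Signal strength of one plane: mean of the brightest pixel fraction
#'
#' Averages the top \code{topFraction} of pixel intensities (default 0.5
#' percent); \code{k = max(1, floor(topFraction * n))} pixels enter the
#' mean, so the metric is well defined on arbitrarily small frames and
#' depends only on the intensity multiset.
#'
#' @param plane 2D numeric matrix
#' @param topFraction fraction of pixels averaged
#' @return mean intensity of the k brightest pixels
#' @export
signalStrength <- function(plane, topFraction = 0.005) {
  v <- as.numeric(plane)
  if (!length(v)) stop("empty plane")
  k <- max(1L, floor(topFraction * length(v)))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Signal-to-background ratio of an intensity profile
#'
#' Mean of the \code{nExtreme} brightest samples over the mean of the
#' \code{nExtreme} darkest (default 15 and 15). An all-zero dark end makes
#' the ratio infinite, signalled with a warning.
#'
#' @param profile numeric vector, length >= 2 * nExtreme
#' @param nExtreme samples averaged at each extreme
#' @return the ratio (>= 1 whenever bright mean >= dark mean)
#' @export
sbr <- function(profile, nExtreme = 15L) {
  v <- as.numeric(profile)
  if (length(v) < 2L * nExtreme)
    stop("profile needs at least ", 2L * nExtreme, " samples")
  s <- sort(v)
  dark <- mean(s[seq_len(nExtreme)])
  bright <- mean(s[seq(length(s) - nExtreme + 1L, length(s))])
  if (dark == 0) {
    warning("infinite SBR: darkest-", nExtreme, " mean is zero")
    return(Inf)
  }
  bright / dark
}

#' Depth profile of signal strength and SBR
#'
#' Per plane: signal strength (top-fraction mean) and the SBR of a line
#' profile through the brightest vessel -- by default the image row through
#' the plane's maximum-intensity pixel, the line-profile convention used for
#' depth-resolved quality reporting. Depth is the plane index times the
#' axial step (origin at the first plane of the, normally dura-removed,
#' stack).
#'
#' @param stack an \linkS4class{ImageStack}
#' @param topFraction fraction for \code{\link{signalStrength}}
#' @param nExtreme extreme-sample count for \code{\link{sbr}}
#' @return data.frame with columns z (0-based index), depth (um),
#'   signalStrength, sbr, channel
#' @export
depthProfile <- function(stack, topFraction = 0.005, nExtreme = 15L) {
  v <- voxels(stack)
  sp <- spacing(stack)
  nz <- dim(v)[1]
  rows <- lapply(seq_len(nz), function(z) {
    plane <- v[z, , ]
    ss <- signalStrength(plane, topFraction)
    pk <- which(plane == max(plane), arr.ind = TRUE)[1, ]
    line <- plane[pk[1], ]
    sb <- if (length(line) >= 2L * nExtreme && min(line) < max(line)) {
      suppressWarnings(sbr(line, nExtreme))
    } else if (min(line) == max(line)) 1.0 else NA_real_
    data.frame(z = z - 1L, depth = (z - 1L) * sp@dz, signalStrength = ss,
               sbr = sb)
  })
  out <- do.call(rbind, rows)
  out$channel <- channelName(stack)
  out
}

#' Full width at half maximum of a peaked profile
#'
#' Baseline is the profile minimum; the half level sits midway between
#' baseline and maximum; the two half-level crossings are located by linear
#' interpolation between bracketing samples and their distance, scaled by
#' the sample spacing, is the FWHM. Used for bead-based resolution
#' measurements.
#'
#' @param profile numeric vector with a peak above its baseline
#' @param spacing physical distance per sample
#' @return width in the units of \code{spacing}
#' @examples
#' x <- seq(-10, 10, by = 1)
#' fwhm(exp(-x^2 / (2 * 2^2)), spacing = 1)   # ~ 2.3548 * 2
#' @export
fwhm <- function(profile, spacing = 1) {
  v <- as.numeric(profile)
  if (length(v) < 3L) stop("profile too short")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("profile has no peak above its baseline")
  half <- lo + (hi - lo) / 2
  pk <- which.max(v)
  left <- NA_real_
  if (pk >= 2L) for (i in pk:2L) {
    if (v[i - 1L] <= half && v[i] > half) {
      left <- (i - 1L) + (half - v[i - 1L]) / (v[i] - v[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (pk <= length(v) - 1L) for (i in pk:(length(v) - 1L)) {
    if (v[i + 1L] <= half && v[i] > half) {
      right <- i + (v[i] - half) / (v[i] - v[i + 1L])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("truncated peak: no half-maximum crossing on ",
         if (is.na(left)) "the left" else "the right")
  (right - left) * spacing
}
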