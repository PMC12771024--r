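#' @include AllClasses.R
NULL

#' Single- and multi-level Otsu thresholds
#'
#' Computes \code{k} intensity thresholds that partition the value histogram
#' into \code{k + 1} classes maximizing the between-class variance, the
#' multilevel generalization of Otsu's method. Solved exactly by dynamic
#' programming over a fixed-bin histogram, so cost is O(k * nBins^2)
#' regardless of volume size.
#'
#' @param x numeric vector (or array) of intensities
#' @param k number of thresholds (1 = classical Otsu)
#' @param nBins histogram resolution
#' @return increasing numeric vector of \code{k} thresholds; a value v
#'   belongs to class \code{findInterval(v, thresholds) + 1}
#' @examples
#' x <- c(rnorm(500, 10, 1), rnorm(500, 50, 1))
#' otsuThresholds(x, 1)   # near 30
#' @export
otsuThresholds <- function(x, k = 1L, nBins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng))) stop("intensities must be finite")
  if (rng[1] == rng[2])
    stop("cannot threshold a constant image")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(pmin(nBins, findInterval(x, breaks, rightmost.closed = TRUE)),
                nbins = nBins)
  mids <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  w <- h / sum(h)
  cw0 <- c(0, cumsum(w))
  cm0 <- c(0, cumsum(w * mids))
  # score of one class spanning bins i..j: omega * mu^2 (vectorized over i)
  classScore <- function(i, j) {
    om <- cw0[j + 1L] - cw0[i]
    mu <- cm0[j + 1L] - cm0[i]
    ifelse(om > 0, mu^2 / om, 0)
  }
  nclass <- k + 1L
  # best[c, j]: max score using classes 1..c over bins 1..j
  best <- matrix(-Inf, nclass, nBins)
  argmin <- matrix(0L, nclass, nBins)
  jj <- seq_len(nBins)
  best[1L, ] <- classScore(1L, jj)
  for (cl in 2L:nclass) {
    for (j in cl:nBins) {
      iopts <- cl:j      # first bin of class cl
      sc <- best[cl - 1L, iopts - 1L] + classScore(iopts, j)
      bi <- which.max(sc)
      best[cl, j] <- sc[bi]
      argmin[cl, j] <- iopts[bi]
    }
  }
  th <- numeric(k)
  j <- nBins
  for (cl in nclass:2L) {
    i <- argmin[cl, j]
    th[cl - 1L] <- breaks[i]   # boundary between class cl-1 and cl
    j <- i - 1L
  }
  th
}

#' Default analysis configuration
#'
#' Every threshold used by the pipeline, overridable from a YAML file via
#' \code{\link{loadConfig}}.
#'
#' @return named list of settings:
#' \describe{
#'   \item{dice_threshold}{Dice QC cutoff below which manual correction is
#'     recommended (0.70)}
#'   \item{min_plaque_area}{plaque area filter in um^2 (49)}
#'   \item{plaque_area_mode}{"max_slice" (default) or "total": which
#'     per-component area the filter tests}
#'   \item{top_fraction}{pixel fraction averaged for signal strength (0.005)}
#'   \item{n_extreme}{profile pixels averaged at each end for SBR (15)}
#'   \item{saturation_fraction}{overexposure cutoff for the normalization
#'     reference plane (0.95)}
#'   \item{clip_limit}{CLAHE relative clip limit (0.01)}
#'   \item{tile_grid}{CLAHE tiles per plane axis (8)}
#'   \item{median_radius}{denoising median-filter radius in voxels (1)}
#'   \item{min_segment_nodes}{skeleton paths shorter than this are pruned
#'     as spurs (3)}
#'   \item{min_component_voxels}{smallest 3D component retained by the
#'     baseline vessel segmenter (27)}
#'   \item{min_object_px}{smallest in-plane object kept during plaque
#'     morphology cleanup (5)}
#'   \item{crosstalk_alpha}{"auto" or a fixed unmixing coefficient}
#'   \item{n_motion_structures}{structures tracked by motion assessment (5)}
#' }
#' @export
defaultConfig <- function() {
  list(
    dice_threshold = 0.70,
    min_plaque_area = 49,
    plaque_area_mode = "max_slice",
    top_fraction = 0.005,
    n_extreme = 15L,
    saturation_fraction = 0.95,
    clip_limit = 0.01,
    tile_grid = 8L,
    median_radius = 1L,
    min_segment_nodes = 3L,
    min_component_voxels = 27L,
    min_object_px = 5L,
    crosstalk_alpha = "auto",
    n_motion_structures = 5L
  )
}

#' Load a configuration file
#'
#' Reads a YAML key-value file and merges it over \code{\link{defaultConfig}};
#' unknown keys are rejected to catch typos.
#'
#' @param path YAML file path, or NULL for pure defaults
#' @return named list as in \code{\link{defaultConfig}}
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

# linear index (1-based) of voxel (z, y, x) in a (nz, ny, nx) array
.linIndex <- function(z, y, x, dims) {
  z + dims[1] * ((y - 1L) + dims[2] * (x - 1L))
}

# physical (x, y, z) coordinates of 1-based voxel indices (z, y, x)
.voxelToPhysical <- function(zyx, sp) {
  cbind(x = (zyx[, 3] - 1) * sp@dx,
        y = (zyx[, 2] - 1) * sp@dy,
        z = (zyx[, 1] - 1) * sp@dz)
}

.checkSameShape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical dimensions (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

.logMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
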