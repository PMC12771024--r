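#' @include AllClasses.R utils.R
NULL

#' Describe one synthetic vessel
#'
#' @param centerline M x 3 matrix of (x, y, z) polyline vertices in
#'   micrometres; consecutive vertices must be distinct
#' @param radius constant tube radius (um)
#' @param intensity peak intensity before depth attenuation
#' @return a \linkS4class{VesselTruth}
#' @export
vesselTruth <- function(centerline, radius, intensity = 10000) {
  new("VesselTruth", centerline = as.matrix(centerline),
      radius = as.numeric(radius), intensity = as.numeric(intensity))
}

#' Analytic length of a ground-truth vessel
#' @param truth a \linkS4class{VesselTruth}
#' @return polyline length, the sum of consecutive vertex distances (um)
#' @export
truthLength <- function(truth) {
  sum(sqrt(rowSums(diff(truth@centerline)^2)))
}

#' Analytic tortuosity of a ground-truth vessel
#' @param truth a \linkS4class{VesselTruth}
#' @return polyline length over endpoint chord
#' @export
truthTortuosity <- function(truth) {
  cl <- truth@centerline
  chord <- sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2))
  if (chord == 0) stop("closed centerline: tortuosity undefined")
  truthLength(truth) / chord
}

#' Describe one synthetic plaque
#'
#' @param center (x, y, z) sphere center (um)
#' @param radius sphere radius (um); analytic volume is (4/3) pi r^3
#' @param intensity peak intensity before depth attenuation
#' @return a \linkS4class{PlaqueTruth}
#' @export
plaqueTruth <- function(center, radius, intensity = 10000) {
  new("PlaqueTruth", center = as.numeric(center), radius = as.numeric(radius),
      intensity = as.numeric(intensity))
}

#' Assemble a phantom specification
#'
#' @param shape (nz, ny, nx) voxel grid
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param vessels list of \linkS4class{VesselTruth}
#' @param plaques list of \linkS4class{PlaqueTruth}
#' @param attenuationLength exponential signal decay length with depth (um);
#'   Inf disables attenuation
#' @param backgroundLevel additive background intensity
#' @param noiseGaussianSD Gaussian read-noise SD (0 disables)
#' @param noisePoisson draw voxel values as Poisson counts first?
#' @param crosstalkAlpha symmetric channel-mixing fraction in [0, 1)
#' @param jitter nz x 2 integer matrix of per-plane (dy, dx) pixel shifts;
#'   NULL for none
#' @param seed RNG seed; identical seeds give identical stacks
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(shape, spacing = voxelSpacing(), vessels = list(),
                        plaques = list(), attenuationLength = Inf,
                        backgroundLevel = 0, noiseGaussianSD = 0,
                        noisePoisson = FALSE, crosstalkAlpha = 0,
                        jitter = NULL, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(jitter)) jitter <- matrix(0L, nrow = shape[1], ncol = 2L)
  new("PhantomSpec", shape = shape, spacing = spacing, vessels = vessels,
      plaques = plaques, attenuationLength = as.numeric(attenuationLength),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseGaussianSD = as.numeric(noiseGaussianSD),
      noisePoisson = isTRUE(noisePoisson),
      crosstalkAlpha = as.numeric(crosstalkAlpha),
      jitter = matrix(as.integer(jitter), ncol = 2L), seed = as.integer(seed))
}

#' Default two-channel phantom: the package's reference study conditions
#'
#' A 256 x 256 x 64 stack at (0.98, 0.98, 5) um sampling containing five
#' in-plane sinusoidal tubes of radius 2 to 5 um at increasing depth (gentle
#' tortuosity 1.0 to ~1.1) and four spheres of radius 8 to 15 um, under an
#' exponential depth attenuation with 300 um decay length and a background
#' at 5 percent of the 10000-count peak. Noise, crosstalk and jitter default
#' off so the geometry is exact; switch them on through the arguments.
#'
#' @param seed RNG seed
#' @param noiseGaussianSD Gaussian read-noise SD (default 0; 1000 = 10
#'   percent of peak is the standard noisy condition)
#' @param noisePoisson Poisson noise flag
#' @param crosstalkAlpha channel mixing fraction
#' @param attenuationLength depth decay length (um)
#' @param jitter per-plane (dy, dx) shifts or NULL
#' @return a \linkS4class{PhantomSpec}
#' @export
defaultPhantomSpec <- function(seed = 1L, noiseGaussianSD = 0,
                               noisePoisson = FALSE, crosstalkAlpha = 0,
                               attenuationLength = 300, jitter = NULL) {
  sp <- voxelSpacing()
  radii <- c(2, 2.75, 3.5, 4.25, 5)
  zPlanes <- c(8, 20, 32, 44, 56)          # 1-based plane -> depth (p-1)*5 um
  y0 <- c(30, 70, 110, 150, 190)
  amp <- c(0, 3, 5, 7, 9)                  # sine amplitude -> tortuosity
  vessels <- lapply(seq_along(radii), function(i) {
    xs <- seq(12, 238, by = 2)
    ys <- y0[i] + amp[i] * sin(2 * pi * (xs - 12) / 110)
    zs <- rep((zPlanes[i] - 1) * sp@dz, length(xs))
    vesselTruth(cbind(xs, ys, zs), radius = radii[i])
  })
  plaques <- list(
    plaqueTruth(c(40, 225, 50), 8),
    plaqueTruth(c(100, 225, 120), 10),
    plaqueTruth(c(160, 225, 200), 12),
    plaqueTruth(c(220, 225, 280), 15))
  phantomSpec(shape = c(64L, 256L, 256L), spacing = sp, vessels = vessels,
              plaques = plaques, attenuationLength = attenuationLength,
              backgroundLevel = 500, noiseGaussianSD = noiseGaussianSD,
              noisePoisson = noisePoisson, crosstalkAlpha = crosstalkAlpha,
              jitter = jitter, seed = seed)
}

# rasterize a tube: set truth/intensity for voxels whose center lies within
# `radius` of the polyline, distance measured in physical um
.rasterTube <- function(truthIdx, intens, vessel, dims, sp) {
  cl <- vessel@centerline
  r <- vessel@radius
  margin <- r + max(sp@dx, sp@dy, sp@dz)
  for (s in seq_len(nrow(cl) - 1L)) {
    a <- cl[s, ]; b <- cl[s + 1L, ]
    lo <- pmin(a, b) - margin; hi <- pmax(a, b) + margin
    ix <- max(1L, floor(lo[1] / sp@dx) + 1L):min(dims[3], ceiling(hi[1] / sp@dx) + 1L)
    iy <- max(1L, floor(lo[2] / sp@dy) + 1L):min(dims[2], ceiling(hi[2] / sp@dy) + 1L)
    iz <- max(1L, floor(lo[3] / sp@dz) + 1L):min(dims[1], ceiling(hi[3] / sp@dz) + 1L)
    g <- expand.grid(z = iz, y = iy, x = ix)
    px <- (g$x - 1) * sp@dx; py <- (g$y - 1) * sp@dy; pz <- (g$z - 1) * sp@dz
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
          (pz - (a[3] + t * ab[3]))^2
    inside <- d2 <= r^2
    if (!any(inside)) next
    li <- .linIndex(g$z[inside], g$y[inside], g$x[inside], dims)
    truthIdx[li] <- TRUE
    intens[li] <- pmax(intens[li], vessel@intensity)
  }
  list(truth = truthIdx, intens = intens)
}

.rasterSphere <- function(labels, intens, plaque, label, dims, sp) {
  ctr <- plaque@center; r <- plaque@radius
  margin <- r + max(sp@dx, sp@dy, sp@dz)
  ix <- max(1L, floor((ctr[1] - margin) / sp@dx) + 1L):min(dims[3], ceiling((ctr[1] + margin) / sp@dx) + 1L)
  iy <- max(1L, floor((ctr[2] - margin) / sp@dy) + 1L):min(dims[2], ceiling((ctr[2] + margin) / sp@dy) + 1L)
  iz <- max(1L, floor((ctr[3] - margin) / sp@dz) + 1L):min(dims[1], ceiling((ctr[3] + margin) / sp@dz) + 1L)
  g <- expand.grid(z = iz, y = iy, x = ix)
  d2 <- ((g$x - 1) * sp@dx - ctr[1])^2 + ((g$y - 1) * sp@dy - ctr[2])^2 +
        ((g$z - 1) * sp@dz - ctr[3])^2
  inside <- d2 <= r^2
  if (any(inside)) {
    li <- .linIndex(g$z[inside], g$y[inside], g$x[inside], dims)
    labels[li] <- label
    intens[li] <- pmax(intens[li], plaque@intensity)
  }
  list(labels = labels, intens = intens)
}

.applyJitter <- function(vox, jitter, fill) {
  dims <- dim(vox)
  for (z in seq_len(dims[1])) {
    dyx <- jitter[z, ]
    if (all(dyx == 0L)) next
    plane <- vox[z, , ]
    out <- matrix(fill, dims[2], dims[3])
    ys <- seq_len(dims[2]) - dyx[1]
    xs <- seq_len(dims[3]) - dyx[2]
    okY <- ys >= 1 & ys <= dims[2]
    okX <- xs >= 1 & xs <= dims[3]
    out[which(okY), which(okX)] <- plane[ys[okY], xs[okX]]
    vox[z, , ] <- out
  }
  vox
}

#' Render a two-channel synthetic phantom with exact ground truth
#'
#' Tubes and spheres are rasterized by exact point-to-geometry distance in
#' physical micrometres; signal is attenuated as \code{exp(-depth /
#' attenuationLength)}, then background is added, then noise (Poisson counts
#' first if enabled, then Gaussian read noise), then symmetric channel
#' crosstalk \code{observed_A = A + alpha * B}, then per-plane integer jitter
#' (edge rows filled with the background level). Truth masks are pre-noise,
#' pre-jitter. Output is reproducible: identical specs (including seed) give
#' voxelwise-identical stacks.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return list with elements \code{vessel}, \code{plaque}
#'   (\linkS4class{ImageStack}), \code{vesselTruth}
#'   (\linkS4class{BinaryMask}), \code{plaqueTruth}
#'   (\linkS4class{LabelVolume}) and \code{spec} (the input echoed)
#' @examples
#' sp <- phantomSpec(c(8, 32, 32), voxelSpacing(1, 1, 1),
#'   vessels = list(vesselTruth(rbind(c(5, 16, 3), c(26, 16, 3)), 2)))
#' ph <- generatePhantom(sp)
#' sum(voxels(ph$vesselTruth))
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  dims <- spec@shape
  sp <- spec@spacing
  bdm <- 65535
  set.seed(spec@seed)

  vTruth <- array(FALSE, dim = dims)
  vInt <- array(0, dim = dims)
  for (v in spec@vessels) {
    res <- .rasterTube(vTruth, vInt, v, dims, sp)
    vTruth <- res$truth; vInt <- res$intens
  }
  pLabels <- array(0L, dim = dims)
  pInt <- array(0, dim = dims)
  for (i in seq_along(spec@plaques)) {
    res <- .rasterSphere(pLabels, pInt, spec@plaques[[i]], i, dims, sp)
    pLabels <- res$labels; pInt <- res$intens
  }

  depth <- (seq_len(dims[1]) - 1) * sp@dz
  atten <- exp(-depth / spec@attenuationLength)
  for (z in seq_len(dims[1])) {
    vInt[z, , ] <- vInt[z, , ] * atten[z]
    pInt[z, , ] <- pInt[z, , ] * atten[z]
  }
  vImg <- vInt + spec@backgroundLevel
  pImg <- pInt + spec@backgroundLevel

  if (spec@noisePoisson) {
    vImg <- array(stats::rpois(length(vImg), lambda = vImg), dim = dims)
    pImg <- array(stats::rpois(length(pImg), lambda = pImg), dim = dims)
  }
  if (spec@noiseGaussianSD > 0) {
    vImg <- vImg + stats::rnorm(length(vImg), sd = spec@noiseGaussianSD)
    pImg <- pImg + stats::rnorm(length(pImg), sd = spec@noiseGaussianSD)
  }

  if (spec@crosstalkAlpha > 0) {
    a <- spec@crosstalkAlpha
    v0 <- vImg
    vImg <- vImg + a * pImg
    pImg <- pImg + a * v0
  }

  anyJitter <- any(spec@jitter != 0L)
  if (anyJitter) {
    vImg <- .applyJitter(vImg, spec@jitter, spec@backgroundLevel)
    pImg <- .applyJitter(pImg, spec@jitter, spec@backgroundLevel)
  }

  vImg <- pmin(pmax(vImg, 0), bdm)
  pImg <- pmin(pmax(pImg, 0), bdm)

  list(
    vessel = imageStack(array(vImg, dims), spacing = sp, channel = "vessel",
                        bitDepthMax = bdm),
    plaque = imageStack(array(pImg, dims), spacing = sp, channel = "plaque",
                        bitDepthMax = bdm),
    vesselTruth = binaryMask(vTruth, spacing = sp),
    plaqueTruth = new("LabelVolume", labels = pLabels, spacing = sp),
    spec = spec)
}
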