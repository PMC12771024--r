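# Shared phantom fixtures; everything is generated in code at test time.

unitSpacing <- function() voxelSpacing(1, 1, 1)

# one z-spanning tube, thick enough that the top-0.5% pool stays inside it
axialTubeSpec <- function(seed = 1, radius = 12, jitter = NULL, alpha = 0,
                          noise = 0, att = 300, plaque = TRUE) {
  plaques <- if (plaque) list(plaqueTruth(c(60, 60, 150), 12)) else list()
  phantomSpec(c(64L, 256L, 256L), voxelSpacing(),
              vessels = list(vesselTruth(rbind(c(122.5, 122.5, 15),
                                               c(122.5, 122.5, 300)), radius)),
              plaques = plaques, attenuationLength = att,
              backgroundLevel = 500, noiseGaussianSD = noise,
              crosstalkAlpha = alpha, jitter = jitter, seed = seed)
}

# small isotropic-ish phantom for fast unit tests
tinyTubeSpec <- function(seed = 1, radius = 3, att = Inf, noise = 0) {
  phantomSpec(c(16L, 48L, 48L), voxelSpacing(1, 1, 2),
              vessels = list(vesselTruth(rbind(c(5, 24, 14), c(42, 24, 14)),
                                         radius)),
              attenuationLength = att, backgroundLevel = 100,
              noiseGaussianSD = noise, seed = seed)
}

# 50 straight tubes with uniformly drawn radii; one imaging session
fiftyTubeSession <- function(seed, shrink = 1) {
  set.seed(seed + 7000)
  radii <- stats::runif(50, 2, 5) * shrink
  slots <- expand.grid(x0 = c(12, 110), y = seq(12, 175, length.out = 5),
                       z = c(30, 80, 130, 180, 230))
  vessels <- lapply(seq_len(50), function(i) {
    s <- slots[i, ]
    vesselTruth(rbind(c(s$x0, s$y, s$z), c(s$x0 + 70, s$y, s$z)), radii[i])
  })
  phantomSpec(c(48L, 192L, 192L), voxelSpacing(), vessels = vessels,
              attenuationLength = 300, backgroundLevel = 500, seed = seed)
}

# crosstalk-estimation fixture: source structure occupies > 1% of voxels
crosstalkSpec <- function(alpha, seed = 3) {
  phantomSpec(c(32L, 128L, 128L), voxelSpacing(1, 1, 2),
              vessels = list(vesselTruth(rbind(c(10, 20, 30), c(117, 20, 30)),
                                         radius = 3)),
              plaques = list(plaqueTruth(c(64, 64, 32), 25)),
              attenuationLength = 300, backgroundLevel = 500,
              crosstalkAlpha = alpha, seed = seed)
}

# brute-force minimum distance from foreground path voxels to background,
# in physical units; the independent oracle for the EDT-based radius profile
bruteRadiusProfile <- function(path, mask) {
  m <- voxels(mask)
  sp <- spacing(mask)
  bg <- which(m == 0L, arr.ind = TRUE)
  bgp <- cbind(bg[, 1] * sp@dz, bg[, 2] * sp@dy, bg[, 3] * sp@dx)
  apply(path, 1, function(p) {
    pp <- c(p[1] * sp@dz, p[2] * sp@dy, p[3] * sp@dx)
    sqrt(min((bgp[, 1] - pp[1])^2 + (bgp[, 2] - pp[2])^2 +
             (bgp[, 3] - pp[3])^2))
  })
}

# segment count oracle: in the skeleton adjacency graph, every maximal
# branch-free path consumes one edge-slot at each of its two terminal ends
segmentCountOracle <- function(skel) {
  g <- morph3p:::.skeletonGraph(skel)
  deg <- lengths(g$nbrs)
  sum(deg[deg != 2L]) / 2
}
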