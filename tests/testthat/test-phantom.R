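test_that("noiseless phantom thresholded at background reproduces the truth mask", {
  spec <- tinyTubeSpec(radius = 3)
  ph <- generatePhantom(spec)
  recon <- voxels(ph$vessel) > spec@backgroundLevel
  expect_identical(array(as.integer(recon), dim(recon)),
                   voxels(ph$vesselTruth))
})

test_that("crosstalk with a structure-free source leaves the target unchanged", {
  mk <- function(alpha) phantomSpec(c(8L, 24L, 24L), unitSpacing(),
    vessels = list(vesselTruth(rbind(c(4, 12, 3), c(20, 12, 3)), 2)),
    plaques = list(), attenuationLength = Inf, backgroundLevel = 0,
    crosstalkAlpha = alpha, seed = 5)
  ph0 <- generatePhantom(mk(0))
  ph3 <- generatePhantom(mk(0.3))
  # plaque channel is all zero, so alpha * plaque adds nothing to vessels
  expect_equal(voxels(ph3$vessel), voxels(ph0$vessel))
  # but the vessel leaks into the plaque channel
  expect_equal(voxels(ph3$plaque), 0.3 * voxels(ph0$vessel))
})

test_that("identical seeds give identical stacks; different seeds differ", {
  a <- generatePhantom(tinyTubeSpec(seed = 4, noise = 50))
  b <- generatePhantom(tinyTubeSpec(seed = 4, noise = 50))
  c <- generatePhantom(tinyTubeSpec(seed = 5, noise = 50))
  expect_identical(voxels(a$vessel), voxels(b$vessel))
  expect_identical(voxels(a$plaque), voxels(b$plaque))
  expect_false(identical(voxels(a$vessel), voxels(c$vessel)))
})

test_that("rasterized tube volume approaches the analytic cylinder volume", {
  sp <- voxelSpacing(1, 1, 2)
  r <- 4                                  # r = 2 * max(spacing)
  spec <- phantomSpec(c(16L, 32L, 64L), sp,
    vessels = list(vesselTruth(rbind(c(6, 16, 14), c(57, 16, 14)), r)),
    attenuationLength = Inf, backgroundLevel = 0, seed = 1)
  ph <- generatePhantom(spec)
  vol <- sum(voxels(ph$vesselTruth)) * voxelVolume(sp)
  # a rasterized tube is a capsule; the cap term vanishes for long tubes
  analytic <- pi * r^2 * 51 + 4 / 3 * pi * r^3
  expect_lt(abs(vol / analytic - 1), 0.10)
})

test_that("mean plane intensity of an attenuating tube never increases with depth", {
  ph <- generatePhantom(axialTubeSpec(att = 300, plaque = FALSE))
  v <- voxels(ph$vessel)
  tubePlanes <- 5:60                      # planes fully inside the tube span
  means <- vapply(tubePlanes, function(z) mean(v[z, , ]), numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("jitter shifts a plane and fills exposed edges with background", {
  jit <- matrix(0L, 16, 2); jit[8, ] <- c(2L, 0L)
  spec <- tinyTubeSpec(seed = 1)
  spec@jitter <- jit
  ph <- generatePhantom(spec)
  ph0 <- generatePhantom(tinyTubeSpec(seed = 1))
  v <- voxels(ph$vessel); v0 <- voxels(ph0$vessel)
  expect_equal(v[8, 3:48, ], v0[8, 1:46, ])
  expect_true(all(v[8, 1:2, ] == spec@backgroundLevel))
  expect_equal(v[7, , ], v0[7, , ])       # other planes untouched
})

test_that("specs violating geometry bounds are rejected", {
  expect_error(phantomSpec(c(8L, 16L, 16L), unitSpacing(),
    vessels = list(vesselTruth(rbind(c(0, 8, 3), c(20, 8, 3)), 2))),
    "beyond the stack bounds")
  expect_error(phantomSpec(c(8L, 16L, 16L), unitSpacing(),
    plaques = list(plaqueTruth(c(8, 8, 7), 4))), "beyond the stack bounds")
  expect_error(phantomSpec(c(8L, 16L, 16L), unitSpacing(),
                           crosstalkAlpha = 1), "crosstalkAlpha")
})

test_that("analytic truth helpers match hand-computed values", {
  vt <- vesselTruth(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)), radius = 2)
  expect_equal(truthLength(vt), 17)
  expect_equal(truthTortuosity(vt), 17 / sqrt(9 + 16 + 144))
  pt <- plaqueTruth(c(10, 10, 10), radius = 3)
  expect_equal(4 / 3 * pi * pt@radius^3, 4 / 3 * pi * 27)
})
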