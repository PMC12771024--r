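entropyBits <- function(p, bdm = 65535) {
  h <- tabulate(pmin(256, findInterval(as.numeric(p),
                                       seq(0, bdm, length.out = 257),
                                       rightmost.closed = TRUE)), 256)
  h <- h[h > 0] / sum(h)
  -sum(h * log2(h))
}

test_that("adaptive equalization honors its range and degenerate-input contracts", {
  const <- imageStack(array(1234, c(2, 64, 64)))
  expect_identical(voxels(adaptiveHistEq(const)), voxels(const))

  set.seed(3)
  v <- array(runif(2 * 64 * 64, 0, 65535), c(2, 64, 64))
  eq <- adaptiveHistEq(imageStack(v))
  expect_gte(min(voxels(eq)), 0)
  expect_lte(max(voxels(eq)), 65535)
  expect_identical(dim(voxels(eq)), dim(v))
})

test_that("equalizing a low-contrast plane increases histogram entropy", {
  set.seed(5)
  plane <- 30000 + 2000 * matrix(sin(seq(0, 4 * pi, length.out = 64)), 64, 64) +
    matrix(rnorm(64 * 64, 0, 200), 64, 64)
  st <- imageStack(array(plane, c(1, 64, 64)))
  eq <- adaptiveHistEq(st)
  expect_gte(entropyBits(voxels(eq)[1, , ]), entropyBits(plane))
})

test_that("crosstalk removal is exact at alpha 0, clamps at zero, and recovers alpha", {
  ph <- generatePhantom(crosstalkSpec(alpha = 0.2))
  same <- removeCrosstalk(ph$vessel, ph$plaque, alpha = 0)
  expect_equal(voxels(same), voxels(ph$vessel))

  est <- removeCrosstalk(ph$vessel, ph$plaque, alpha = "auto")
  expect_lt(abs(attr(est, "alpha") - 0.2), 0.05)

  # target everywhere below alpha * source clamps to zero
  tgt <- imageStack(array(10, c(2, 8, 8)))
  src <- imageStack(array(1000, c(2, 8, 8)))
  expect_true(all(voxels(removeCrosstalk(tgt, src, alpha = 0.5)) == 0))

  expect_error(removeCrosstalk(tgt, imageStack(array(0, c(2, 8, 9)))),
               "identical dimensions")
})

test_that("dura removal trims exactly the requested shallow planes", {
  v <- array(seq_len(64 * 8 * 8), c(64, 8, 8)) / 10
  st <- imageStack(v, bitDepthMax = 65535)
  expect_equal(voxels(removeDura(st, 0)), v)
  cut <- removeDura(st, 3)
  expect_identical(dim(voxels(cut))[1], 61L)
  expect_equal(voxels(cut)[1, , ], v[4, , ])
  expect_error(removeDura(st, 64), "smaller than the plane count")
})

test_that("a bright superficial THG band localizes the dura boundary", {
  thgv <- array(100, c(64, 16, 16)); thgv[1:3, , ] <- 5000
  thg <- imageStack(thgv, channel = "thg")
  st <- imageStack(array(runif(64 * 16 * 16, 0, 1000), c(64, 16, 16)))
  out <- removeDura(st, "from-thg", thg)
  expect_identical(attr(out, "boundary"), 3L)
  expect_identical(dim(voxels(out))[1], 61L)
  expect_error(removeDura(st, "from-thg"), "requires a THG stack")
})

test_that("normalization maps every plane onto the reference plane's range", {
  # two-plane case solved by hand
  v <- array(0, c(2, 8, 8))
  v[1, , ] <- seq(0, 65535, length.out = 64)
  v[2, , ] <- seq(100, 0.5 * 65535, length.out = 64)
  nn <- normalizeStack(imageStack(v))
  expect_identical(attr(nn, "referencePlane"), 2L)
  expect_equal(max(voxels(nn)[1, , ]), 0.5 * 65535)
  expect_equal(min(voxels(nn)[1, , ]), 100)
  expect_equal(voxels(nn)[2, , ], v[2, , ])

  # stack already sharing the reference range is unchanged
  same <- array(rep(seq(0, 30000, length.out = 64), each = 3), c(3, 8, 8))
  expect_equal(voxels(normalizeStack(imageStack(same))), same)

  # attenuating phantom: per-plane maxima equalized to within 5 percent
  ph <- generatePhantom(axialTubeSpec(att = 300, plaque = FALSE))
  nph <- normalizeStack(ph$vessel)
  tubePlanes <- 5:60
  maxes <- vapply(tubePlanes, function(z) max(voxels(nph)[z, , ]), numeric(1))
  expect_lt(diff(range(maxes)) / max(maxes), 0.05)
})

test_that("median denoising removes impulses and reduces phantom RMSE", {
  const <- imageStack(array(777, c(4, 8, 8)), spacing = unitSpacing())
  expect_equal(voxels(denoiseStack(const)), voxels(const))

  imp <- array(100, c(5, 9, 9)); imp[3, 5, 5] <- 60000
  st <- imageStack(imp, spacing = unitSpacing())
  expect_equal(voxels(denoiseStack(st, radius = 1))[3, 5, 5], 100)

  clean <- generatePhantom(tinyTubeSpec(seed = 8, noise = 0))
  noisy <- generatePhantom(tinyTubeSpec(seed = 8, noise = 300))
  den <- denoiseStack(noisy$vessel, radius = 1)
  rmse <- function(a, b) sqrt(mean((voxels(a) - voxels(b))^2))
  expect_lt(rmse(den, clean$vessel), rmse(noisy$vessel, clean$vessel))
})

test_that("motion assessment reports zero for static stacks and the injected jitter", {
  ph <- generatePhantom(axialTubeSpec(plaque = FALSE))
  rep0 <- assessMotion(ph$vessel)
  expect_equal(maxShift(rep0), 0, tolerance = 1e-9)

  jit <- matrix(0L, 64, 2); jit[30, ] <- c(0L, 3L)
  phj <- generatePhantom(axialTubeSpec(jitter = jit, plaque = FALSE))
  repj <- assessMotion(phj$vessel)
  expect_equal(maxShift(repj), 3, tolerance = 0.5)
  sh <- motionShifts(repj)
  expect_equal(maxShift(repj), max(sh$shift))

  expect_error(assessMotion(imageStack(array(0, c(4, 8, 8)))),
               "no foreground")
})

test_that("preprocessing preserves stack shape except dura removal", {
  ph <- generatePhantom(tinyTubeSpec(seed = 2, noise = 100))
  d0 <- dim(voxels(ph$vessel))
  expect_identical(dim(voxels(adaptiveHistEq(ph$vessel))), d0)
  expect_identical(dim(voxels(normalizeStack(ph$vessel))), d0)
  expect_identical(dim(voxels(denoiseStack(ph$vessel))), d0)
  expect_identical(dim(voxels(removeDura(ph$vessel, 2)))[2:3], d0[2:3])
})
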