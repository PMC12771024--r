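test_that("Dice coefficient matches its closed form and QC flag rule", {
  a <- binaryMask(array(c(rep(1, 8), rep(0, 8)), c(1, 4, 4)), unitSpacing())
  expect_equal(as.numeric(diceCoefficient(a, a)), 1)
  expect_null(attr(diceCoefficient(a, a), "flag"))

  b <- binaryMask(array(c(rep(0, 8), rep(1, 8)), c(1, 4, 4)), unitSpacing())
  d0 <- diceCoefficient(a, b)
  expect_equal(as.numeric(d0), 0)
  expect_match(attr(d0, "flag"), "manual correction")

  # |pred| = |truth| = 100, overlap 50 -> 0.5, flagged
  p <- array(0L, c(2, 10, 10)); p[1, , ] <- 1L
  t <- array(0L, c(2, 10, 10)); t[1, 6:10, ] <- 1L; t[2, 1:5, ] <- 1L
  d <- diceCoefficient(binaryMask(p, unitSpacing()),
                       binaryMask(t, unitSpacing()))
  expect_equal(as.numeric(d), 0.5)
  expect_match(attr(d, "flag"), "manual correction")

  empty <- binaryMask(array(0L, c(2, 10, 10)), unitSpacing())
  expect_error(diceCoefficient(empty, empty), "both masks are empty")
})

test_that("baseline Otsu segmentation recovers the noiseless phantom and its inverse", {
  ph <- generatePhantom(tinyTubeSpec(radius = 3))
  seg <- baselineSegment(ph$vessel)
  expect_gte(as.numeric(diceCoefficient(seg, ph$vesselTruth)), 0.95)

  inv <- imageStack(max(voxels(ph$vessel)) - voxels(ph$vessel),
                    spacing = spacing(ph$vessel))
  segInv <- baselineSegment(inv, invert = TRUE)
  expect_identical(voxels(segInv), voxels(seg))

  expect_error(baselineSegment(imageStack(array(5, c(2, 8, 8)))), "constant")
  # a lone bright voxel is removed by the component filter: empty result
  speck <- array(100, c(4, 8, 8)); speck[2, 4, 4] <- 5000
  expect_warning(baselineSegment(imageStack(speck)), "empty mask")
})

test_that("skeletonization is identity on thin lines and centers thick tubes", {
  line <- array(0L, c(3, 3, 12)); line[2, 2, 2:11] <- 1L
  sk <- skeletonize(binaryMask(line, unitSpacing()))
  expect_identical(voxels(sk), line)

  cyl <- array(0L, c(9, 9, 40))
  for (x in 1:40) for (y in 1:9) for (z in 1:9)
    if ((y - 5)^2 + (z - 5)^2 <= 9) cyl[z, y, x] <- 1L
  skc <- voxels(skeletonize(binaryMask(cyl, unitSpacing())))
  co <- which(skc == 1L, arr.ind = TRUE)
  expect_true(all(abs(co[, 1] - 5) <= 1))
  expect_true(all(abs(co[, 2] - 5) <= 1))

  two <- array(0L, c(3, 9, 12)); two[2, 2, 2:11] <- 1L; two[2, 8, 2:11] <- 1L
  skt <- skeletonize(binaryMask(two, unitSpacing()))
  lab <- morph3p:::.label3d(voxels(skt), dim(voxels(skt)), 26L)
  expect_identical(max(lab), 2L)

  expect_error(skeletonize(binaryMask(array(0L, c(2, 2, 2)), unitSpacing())),
               "empty mask")
})

test_that("segment splitting matches forced topologies and the terminal-degree oracle", {
  line <- array(0L, c(3, 3, 12)); line[2, 2, 2:11] <- 1L
  skl <- new("Skeleton", voxels = line, spacing = unitSpacing())
  paths <- splitSegments(skl)
  expect_length(paths, 1L)
  expect_identical(nrow(paths[[1]]), 10L)

  # symmetric Y: three arms meeting at one branch point
  y <- array(0L, c(1, 20, 20))
  y[1, 10, 2:10] <- 1L
  for (i in 1:7) { y[1, 10 + i, 10 + i] <- 1L; y[1, 10 - i, 10 + i] <- 1L }
  sky <- new("Skeleton", voxels = y, spacing = unitSpacing())
  expect_length(splitSegments(sky, minNodes = 2), 3L)
  expect_equal(length(splitSegments(sky, minNodes = 2)),
               segmentCountOracle(sky))

  # random branching structure from crossing phantom tubes
  spec <- phantomSpec(c(10L, 60L, 60L), unitSpacing(),
    vessels = list(
      vesselTruth(rbind(c(5, 30, 5), c(55, 30, 5)), 2),
      vesselTruth(rbind(c(30, 5, 5), c(30, 55, 5)), 2),
      vesselTruth(rbind(c(8, 8, 5), c(50, 52, 5)), 2)),
    attenuationLength = Inf, backgroundLevel = 0, seed = 2)
  ph <- generatePhantom(spec)
  sk <- skeletonize(ph$vesselTruth)
  expect_equal(length(splitSegments(sk, minNodes = 1)),
               segmentCountOracle(sk))
})

test_that("radius profiles equal the brute-force background scan, including anisotropy", {
  set.seed(11)
  m <- array(as.integer(runif(16 * 14 * 12) > 0.35), c(16, 14, 12))
  m[8, 7, ] <- 1L                       # guaranteed foreground path
  m[1, 1, 1] <- 0L                      # guarantee background exists
  mask <- binaryMask(m, voxelSpacing(0.7, 1.1, 2.3))
  path <- cbind(8, 7, 1:12)
  expect_equal(vesselRadiusProfile(path, mask),
               bruteRadiusProfile(path, mask), tolerance = 1e-12)

  # axial line with background only in z-adjacent planes: r = dz = 5
  m2 <- array(0L, c(3, 4, 10)); m2[2, , ] <- 1L
  mask2 <- binaryMask(m2, voxelSpacing(1, 1, 5))
  path2 <- cbind(2, 2, 3:8)
  expect_equal(vesselRadiusProfile(path2, mask2), rep(5, 6))

  # 1-voxel line in background at unit spacing: interior radius 1
  m3 <- array(0L, c(5, 5, 9)); m3[3, 3, 2:8] <- 1L
  r3 <- vesselRadiusProfile(cbind(3, 3, 3:7), binaryMask(m3, unitSpacing()))
  expect_equal(r3, rep(1, 5))

  full <- binaryMask(array(1L, c(2, 2, 2)), unitSpacing())
  expect_error(vesselRadiusProfile(cbind(1, 1, 1), full), "no background")
})

test_that("diameter, length and tortuosity follow their definitions", {
  expect_equal(vesselDiameter(c(3, 3, 3)), 6)
  expect_equal(vesselDiameter(c(1, 2, 3, 4)), 5)   # even-count median
  expect_error(vesselDiameter(numeric(0)), "empty")

  expect_equal(vesselLength(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(vesselLength(cbind(seq(0, 9.8, by = 0.98), 0, 0)), 9.8)
  set.seed(3)
  pts <- matrix(rnorm(150), ncol = 3)
  oracle <- sum(vapply(seq_len(49), function(i)
    sqrt(sum((pts[i + 1, ] - pts[i, ])^2)), numeric(1)))
  expect_equal(vesselLength(pts), oracle, tolerance = 1e-12)
  expect_error(vesselLength(pts[1, , drop = FALSE]), "2 points")

  straight <- cbind(seq(0, 10, length.out = 7), 2, 5)
  expect_equal(vesselTortuosity(straight), 1, tolerance = 1e-9)
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(20 * cos(th), 20 * sin(th), 0)
  expect_equal(vesselTortuosity(semi), pi / 2, tolerance = 0.02 * pi / 2)
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_error(vesselTortuosity(loop), "undefined tortuosity")
})

test_that("total vascular volume is exactly count times voxel volume", {
  empty <- binaryMask(array(0L, c(2, 4, 4)), voxelSpacing())
  expect_equal(as.numeric(totalVesselVolume(empty)), 0)

  set.seed(4)
  m <- array(as.integer(runif(10 * 20 * 20) > 0.7), c(10, 20, 20))
  mask <- binaryMask(m, voxelSpacing())
  v <- totalVesselVolume(mask)
  expect_equal(as.numeric(v), sum(m) * 0.98 * 0.98 * 5)
  expect_equal(attr(v, "nVoxels"), sum(m))
  expect_equal(as.numeric(v) / voxelVolume(mask), sum(m))   # Eq. 5 identity

  # rasterized tubes are capsules (hemispherical end caps on the cylinder)
  ph <- generatePhantom(tinyTubeSpec(radius = 4))
  vol <- as.numeric(totalVesselVolume(ph$vesselTruth))
  capsule <- pi * 16 * 37 + 4 / 3 * pi * 64
  expect_lt(abs(vol / capsule - 1), 0.10)
})

test_that("inter-vessel distance is the nearest-centroid distance, permutation-invariant", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(interVesselDistance(two), c(10, 10))

  three <- rbind(c(0, 0, 0), c(5, 0, 0), c(12, 0, 0))
  expect_equal(interVesselDistance(three), c(5, 5, 7))

  set.seed(6)
  cents <- matrix(runif(60, 0, 200), ncol = 3)
  ivd <- interVesselDistance(cents)
  oracle <- vapply(1:20, function(i) {
    min(vapply(setdiff(1:20, i), function(j)
      sqrt(sum((cents[i, ] - cents[j, ])^2)), numeric(1)))
  }, numeric(1))
  expect_equal(ivd, oracle, tolerance = 1e-12)

  perm <- sample(20)
  expect_equal(interVesselDistance(cents[perm, ]), ivd[perm])
  expect_error(interVesselDistance(cents[1, , drop = FALSE]), "at least 2")
})

test_that("metrics scale linearly (and volume cubically) with spacing", {
  spec <- phantomSpec(c(12L, 40L, 40L), unitSpacing(),
    vessels = list(vesselTruth(rbind(c(5, 12, 6), c(35, 30, 6)), 2.5)),
    attenuationLength = Inf, backgroundLevel = 0, seed = 9)
  ph <- generatePhantom(spec)
  m <- voxels(ph$vesselTruth)
  s1 <- vesselMorphometry(binaryMask(m, unitSpacing()), minSegmentLength = 2)
  s2 <- vesselMorphometry(binaryMask(m, voxelSpacing(2, 2, 2)),
                          minSegmentLength = 4)
  m1 <- segmentMetrics(s1); m2 <- segmentMetrics(s2)
  expect_equal(m2$diameter, 2 * m1$diameter, tolerance = 1e-9)
  expect_equal(m2$length, 2 * m1$length, tolerance = 1e-9)
  expect_equal(m2$tortuosity, m1$tortuosity, tolerance = 1e-9)
  expect_equal(totalVolume(s2), 8 * totalVolume(s1), tolerance = 1e-12)
})
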