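# small isotropic-ish phantom with three well-separated bright spheres
threeSphereSpec <- function(seed = 1, att = Inf) {
  phantomSpec(c(24L, 64L, 64L), voxelSpacing(1, 1, 2),
              plaques = list(plaqueTruth(c(15, 15, 12), 6),
                             plaqueTruth(c(45, 20, 30), 8),
                             plaqueTruth(c(30, 48, 22), 7)),
              attenuationLength = att, backgroundLevel = 100, seed = seed)
}

test_that("multilevel Otsu segmentation labels each bright sphere once", {
  ph <- generatePhantom(threeSphereSpec())
  labs <- segmentPlaques(ph$plaque)
  expect_identical(max(voxels(labs)), 3L)
  # each truth sphere maps to exactly one label
  truth <- voxels(ph$plaqueTruth)
  for (k in 1:3) {
    got <- unique(voxels(labs)[truth == k])
    got <- got[got > 0]
    expect_length(got, 1L)
  }
  expect_error(segmentPlaques(imageStack(array(7, c(2, 8, 8)))), "constant")
  emptyMask <- binaryMask(array(0L, c(2, 8, 8)), unitSpacing())
  expect_warning(segmentPlaques(mode = "manual_mask", manual = emptyMask),
                 "empty")
  expect_error(segmentPlaques(mode = "manual_mask"), "requires a mask")
})

test_that("the area filter applies the 49 um^2 rule to the largest slice, strictly", {
  mkLabels <- function(pixelCounts) {
    # one single-plane component per entry, well separated
    lab <- array(0L, c(2, 40, 200))
    x0 <- 1L
    for (i in seq_along(pixelCounts)) {
      n <- pixelCounts[i]
      w <- ceiling(n / 20)
      cells <- cbind(rep(1L, n), rep(1:20, length.out = n) + 5L,
                     x0 + rep(seq_len(w), each = 20)[seq_len(n)])
      lab[cells] <- i
      x0 <- x0 + w + 5L
    }
    new("LabelVolume", labels = lab, spacing = voxelSpacing())
  }
  labs <- mkLabels(c(60, 40, 51, 52))
  filt <- filterSmallRegions(labs, minArea = 49)
  kept <- sort(unique(as.integer(voxels(filt)[voxels(labs) > 0])))
  # 60 px = 57.62 kept; 40 px = 38.42 removed;
  # 51 px = 48.98 removed; 52 px = 49.94 kept (strict < exclusion)
  remap <- vapply(1:4, function(i) {
    g <- unique(voxels(filt)[voxels(labs) == i]); g[g > 0][1] }, numeric(1))
  expect_false(is.na(remap[1]))
  expect_true(is.na(remap[2]))
  expect_true(is.na(remap[3]))
  expect_false(is.na(remap[4]))
  # labels re-indexed contiguously and filtering is idempotent
  expect_identical(sort(unique(as.integer(voxels(filt)[voxels(filt) > 0]))),
                   c(1L, 2L))
  again <- filterSmallRegions(filt, minArea = 49)
  expect_identical(voxels(again), voxels(filt))
})

test_that("plaque volume is summed slice area times the axial step", {
  lab <- array(0L, c(3, 20, 20))
  lab[1, 1:10, 1:10] <- 1L                       # 100 px in one plane
  lv <- new("LabelVolume", labels = lab, spacing = voxelSpacing())
  expect_equal(as.numeric(plaqueVolumes(lv)), 100 * 0.98^2 * 5)

  lab2 <- array(0L, c(3, 20, 20))
  lab2[1, 1:5, 1:10] <- 1L; lab2[2, 1:5, 1:10] <- 1L   # 2 planes x 50 px
  lv2 <- new("LabelVolume", labels = lab2, spacing = voxelSpacing())
  expect_equal(as.numeric(plaqueVolumes(lv2)), 100 * 0.98^2 * 5)
})

test_that("equivalent-sphere radius inverts the sphere volume identity", {
  expect_equal(plaqueRadius(4 * pi / 3), 1)
  expect_equal(plaqueRadius(4188.790205), 10, tolerance = 1e-6)
  r <- c(0.5, 3, 11.2)
  expect_equal(plaqueRadius(4 / 3 * pi * r^3), r, tolerance = 1e-9)
  expect_error(plaqueRadius(0), "strictly positive")
})

test_that("sphere radii are recovered within tolerance from segmented phantoms", {
  ph <- generatePhantom(threeSphereSpec())
  labs <- filterSmallRegions(segmentPlaques(ph$plaque))
  pm <- plaqueMorphometry(labs)
  expect_identical(nrow(pm), 3L)
  est <- sort(pm$equivalentRadius)
  expect_equal(est, c(6, 7, 8), tolerance = 0.12)
  # centroid accuracy: each within one voxel of the truth center
  truthCenters <- rbind(c(15, 15, 12), c(30, 48, 22), c(45, 20, 30))
  got <- as.matrix(pm[order(pm$equivalentRadius),
                      c("centroid_x", "centroid_y", "centroid_z")])
  expect_lt(max(abs(got - truthCenters)), 2)
})

test_that("nearest plaque-vessel distances match the exhaustive voxel scan", {
  m <- array(0L, c(6, 10, 10)); m[3, 4, 7] <- 1L
  mask <- binaryMask(m, voxelSpacing(1, 1, 5))
  # centroid exactly on the vessel voxel: (x,y,z) = ((7-1)*1, (4-1)*1, (3-1)*5)
  expect_equal(nearestPlaqueVesselDistance(rbind(c(6, 3, 10)), mask), 0)
  # one plane above (dz = 5)
  expect_equal(nearestPlaqueVesselDistance(rbind(c(6, 3, 5)), mask), 5)

  set.seed(12)
  mr <- array(as.integer(runif(8 * 12 * 12) > 0.9), c(8, 12, 12))
  mr[2, 3, 4] <- 1L
  maskR <- binaryMask(mr, voxelSpacing(0.98, 0.98, 5))
  pts <- cbind(runif(5, 0, 10), runif(5, 0, 10), runif(5, 0, 30))
  fg <- which(mr == 1L, arr.ind = TRUE)
  fgp <- cbind((fg[, 3] - 1) * 0.98, (fg[, 2] - 1) * 0.98, (fg[, 1] - 1) * 5)
  oracle <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(fgp) - p)^2))))
  expect_equal(nearestPlaqueVesselDistance(pts, maskR), oracle,
               tolerance = 1e-12)

  empty <- binaryMask(array(0L, c(2, 4, 4)), unitSpacing())
  expect_error(nearestPlaqueVesselDistance(rbind(c(1, 1, 1)), empty),
               "empty")
})

test_that("plaque morphometry tables are complete and spacing-aware", {
  ph <- generatePhantom(threeSphereSpec())
  vm <- binaryMask(array(c(1L, rep(0L, 24 * 64 * 64 - 1)), c(24, 64, 64)),
                   voxelSpacing(1, 1, 2))
  labs <- filterSmallRegions(segmentPlaques(ph$plaque))
  pm <- plaqueMorphometry(labs, vesselMask = vm)
  expect_true(all(c("volume", "equivalentRadius", "maxSliceArea",
                    "nearestVesselDistance") %in% names(pm)))
  expect_true(all(pm$nearestVesselDistance > 0))
  expect_true(all(pm$maxSliceArea >= 49))
})
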