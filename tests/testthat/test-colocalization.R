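test_that("channel binarization respects the threshold method", {
  m <- matrix(c(0, 40, 60, 0, 100, 100), 2)
  fx <- binarizeChannel(m, method = "fixed", value = 50, pixelSizeXY = 0.1)
  expect_identical(as.vector(pixels(fx)), as.vector(m > 50))
  expect_identical(thresholdUsed(fx), 50)
  two <- binarizeChannel(matrix(c(0, 0, 100, 100, 0, 100), 2),
                         method = "otsu", pixelSizeXY = 0.1)
  expect_identical(as.vector(pixels(two)),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  none <- binarizeChannel(matrix(c(1, 2, 3), 1), method = "fixed",
                          value = 10, pixelSizeXY = 0.1)
  expect_false(any(pixels(none)))
  expect_error(binarizeChannel(matrix(7, 3, 3), method = "otsu"), "constant")
})

test_that("overlap fraction equals the brute-force intersection count", {
  for (s in 1:30) {
    mp <- randomMaskPair(s)
    res <- overlapFraction(mp$ref, mp$sel)
    nInt <- oracleOverlapCount(mp$ref@pixels, mp$sel@pixels)
    expect_identical(overlapFractionValue(res), nInt / sum(mp$ref@pixels))
    expect_equal(intersectArea(res), nInt * 0.01)
  }
  ## all-true / all-false selections
  mp <- randomMaskPair(99)
  allT <- mp$sel; allT@pixels[] <- TRUE
  allF <- mp$sel; allF@pixels[] <- FALSE
  expect_identical(overlapFractionValue(overlapFraction(mp$ref, allT)), 1)
  expect_identical(overlapFractionValue(overlapFraction(mp$ref, allF)), 0)
  expect_error(overlapFraction(allF, mp$sel), "empty")
})

test_that("shrinking the selection mask never increases the intersection", {
  for (s in 1:10) {
    mp <- randomMaskPair(s + 500)
    res <- overlapFraction(mp$ref, mp$sel)
    shr <- mp$sel
    on <- which(shr@pixels)
    if (length(on) > 1) {
      set.seed(s)
      shr@pixels[sample(on, ceiling(length(on) / 3))] <- FALSE
    }
    expect_lte(intersectArea(overlapFraction(mp$ref, shr)),
               intersectArea(res))
  }
})

test_that("large-cluster coverage counts covered qualifying clusters", {
  lab <- matrix(0L, 20, 40)
  for (k in 1:10) lab[6:9, (4 * k - 3):(4 * k - 1)] <- k  # 12 px each
  cs <- new("ClusterSet", labels = lab,
            areas = setNames(rep(12 * 0.01, 10), 1:10),
            thresholdUsed = 1, excludedBorderLabels = integer(),
            pixelSizeXY = 0.1)
  gm <- matrix(FALSE, 20, 40)
  for (k in 1:7) gm[6, 4 * k - 3] <- TRUE  # caps on clusters 1..7
  gmask <- new("BinaryMask", pixels = array(gm, dim(gm)), pixelSizeXY = 0.1,
               thresholdMethod = "fixed", thresholdValue = 0)
  res <- largeClusterCoverage(cs, gmask, areaThreshold = 0.1)
  expect_identical(res$fraction, 0.7)
  expect_identical(res$nQualifying, 10L)
  ## no qualifying cluster is distinct from zero coverage
  none <- largeClusterCoverage(cs, gmask, areaThreshold = 10)
  expect_true(is.na(none$fraction))
  expect_identical(none$nQualifying, 0L)
  ## minOverlapPx above the single overlapping pixel de-covers everything
  strict <- largeClusterCoverage(cs, gmask, areaThreshold = 0.1,
                                 minOverlapPx = 2L)
  expect_identical(strict$fraction, 0)
})

test_that("scene coverage measurement hits the generated extremes", {
  full <- measureSceneCoverage(simulateScene(seed = 41))
  expect_identical(full$fraction, 1)
  none <- measureSceneCoverage(simulateScene(
    granuleParams = GranuleParams(coverageFraction = 0), seed = 43))
  expect_identical(none$fraction, 0)
})

test_that("center-of-mass distances are exact, symmetric, homogeneous", {
  d <- c(9, 9, 5)
  ia <- array(0, d); ib <- array(0, d)
  ma <- array(FALSE, d); mb <- array(FALSE, d)
  ia[4, 2, 3] <- 7; ma[4, 2, 3] <- TRUE
  ib[4, 7, 3] <- 3; mb[4, 7, 3] <- TRUE
  ## 5 voxels apart along x at 0.2 um/voxel
  res <- comDistance(ia, ma, ib, mb, voxelSize = c(0.2, 0.2, 0.5))
  expect_equal(res$distance, 1.0)
  ## identical granule: zero distance
  expect_identical(comDistance(ia, ma, ia, ma)$distance, 0)
  ## symmetry and intensity homogeneity
  rev <- comDistance(ib, mb, ia, ma, voxelSize = c(0.2, 0.2, 0.5))
  expect_identical(rev$distance, res$distance)
  dbl <- comDistance(2 * ia, ma, 2 * ib, mb, voxelSize = c(0.2, 0.2, 0.5))
  expect_identical(dbl$distance, res$distance)
  expect_error(comDistance(ia, array(FALSE, d), ib, mb), "empty")
})

test_that("focus counting detects separated spots and merges close ones", {
  blank <- matrix(0, 40, 40)
  expect_identical(countFociPlane(blank)$count, 0L)
  spot <- function(img, y, x, amp = 100) {
    for (dy in -2:2) for (dx in -2:2)
      img[y + dy, x + dx] <- img[y + dy, x + dx] +
        amp * exp(-(dy^2 + dx^2) / 2)
    img
  }
  img <- matrix(0, 40, 40)
  pos <- rbind(c(8, 8), c(8, 30), c(20, 20), c(33, 10), c(33, 32))
  for (i in 1:5) img <- spot(img, pos[i, 1], pos[i, 2])
  expect_identical(countFociPlane(img)$count, 5L)
  ## two spots inside the smoothing scale merge into one detection
  close2 <- spot(spot(matrix(0, 40, 40), 20, 20), 20, 22)
  expect_identical(countFociPlane(close2)$count, 1L)
})

test_that("rachis fraction partitions granule area between compartments", {
  plane <- matrix(0, 20, 20)
  rachis <- matrix(FALSE, 20, 20); rachis[, 8:13] <- TRUE
  nuclei <- matrix(FALSE, 20, 20); nuclei[, c(1:7, 14:20)] <- TRUE
  ## 30 granule px in rachis, 90 in nuclei region -> 0.25
  plane[1:10, 9:11] <- 100      # 30 px in rachis
  plane[3:11, 2:6] <- 100       # 45 px
  plane[12:20, 16:20] <- 100    # 45 px
  res <- rachisGranuleFraction(plane, rachis, nuclei, method = "fixed",
                               value = 50)
  expect_identical(res$fraction, 0.25)
  ## extremes
  inR <- matrix(0, 20, 20); inR[5, 9] <- 100
  expect_identical(rachisGranuleFraction(inR, rachis, nuclei,
                                         method = "fixed",
                                         value = 50)$fraction, 1)
  inN <- matrix(0, 20, 20); inN[5, 2] <- 100
  expect_identical(rachisGranuleFraction(inN, rachis, nuclei,
                                         method = "fixed",
                                         value = 50)$fraction, 0)
  ## zero granule area is undefined, not zero
  expect_true(is.na(rachisGranuleFraction(matrix(0, 20, 20), rachis, nuclei,
                                          method = "fixed",
                                          value = 50)$fraction))
  expect_error(rachisGranuleFraction(plane, rachis, rachis), "disjoint")
})
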