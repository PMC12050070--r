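roiSquare <- function(nr, nc, ys, xs) {
  m <- matrix(FALSE, nr, nc); m[ys, xs] <- TRUE; m
}

test_that("background-subtracted integrated density matches arithmetic", {
  ## roi sum 1000 over 100 px, bg mean 2 -> 800
  img <- matrix(2, 30, 30)
  img[1:10, 1:10] <- 10
  roi <- roiSquare(30, 30, 1:10, 1:10)
  bg <- roiSquare(30, 30, 20:24, 20:24)
  res <- integratedDensityBgsub(img, roi, bg)
  expect_identical(res$corrected, 800)
  expect_identical(res$area, 100L)
  ## uniform image corrects to zero
  expect_identical(integratedDensityBgsub(matrix(5, 10, 10),
                                          roiSquare(10, 10, 1:3, 1:3),
                                          roiSquare(10, 10, 6:8, 6:8))$corrected,
                   0)
  ## offset invariance, exact
  off <- integratedDensityBgsub(img + 13.5, roi, bg)
  expect_equal(off$corrected, res$corrected)
  ## oracle equivalence with three unequal regions, both bg modes
  set.seed(8)
  img2 <- matrix(runif(900, 0, 50), 30)
  bgs <- list(roiSquare(30, 30, 15:16, 1:8), roiSquare(30, 30, 25:29, 25:29),
              roiSquare(30, 30, 1:2, 25:30))
  expect_equal(integratedDensityBgsub(img2, roi, bgs)$corrected,
               oracleBgsubIntegratedDensity(img2, roi, bgs))
  pooled <- integratedDensityBgsub(img2, roi, bgs, bgMode = "pooled")
  poolMask <- bgs[[1]] | bgs[[2]] | bgs[[3]]
  expect_equal(pooled$corrected,
               sum(img2[roi]) - mean(img2[poolMask]) * 100)
  expect_error(integratedDensityBgsub(img2, roi, list()), "background")
  expect_error(integratedDensityBgsub(img2, roi, roi), "disjoint")
})

test_that("nucleus panel ratios normalize to the second germline nucleus", {
  m <- function(corr, area) list(corrected = corr, area = area)
  out <- nucleusPanelRatios(m(200, 50), m(100, 50), m(50, 50))
  expect_equal(out$normalized, c(2, 1, 0.5))
  expect_equal(out$perAreaNormalized, c(2, 1, 0.5))
  ## all equal -> all ones
  eq <- nucleusPanelRatios(m(100, 40), m(100, 40), m(100, 40))
  expect_true(all(eq$normalized == 1))
  ## common gain cancels
  sc <- nucleusPanelRatios(m(600, 50), m(300, 50), m(150, 50))
  expect_equal(sc$normalized, out$normalized)
  ## per-area differs from integrated when areas differ
  pa <- nucleusPanelRatios(m(200, 100), m(100, 50), m(50, 25))
  expect_equal(pa$normalized, c(2, 1, 0.5))
  expect_equal(pa$perAreaNormalized, c(1, 1, 1))
  expect_error(nucleusPanelRatios(m(1, 1), m(0, 1), m(1, 1)), "nonpositive")
})

test_that("FISH levels recover the generator truth ratio", {
  bgs <- list(roiSquare(96, 96, 2:7, 2:7), roiSquare(96, 96, 2:7, 88:93),
              roiSquare(96, 96, 88:93, 2:7))
  ## identical channels -> normalized 1
  f <- renderFishField(FishFieldParams(targetMean = 50, controlMean = 50),
                       seed = 1, noise = FALSE)
  roi <- f$germlineMask
  expect_equal(fishLevel(f$target, f$control, roi, bgs)$normalized, 1)
  ## truth ratio 1.5, noise off, within 0.01
  f <- renderFishField(FishFieldParams(targetMean = 75, controlMean = 50),
                       seed = 2, noise = FALSE)
  expect_lt(abs(fishLevel(f$target, f$control, roi, bgs)$ratio - 1.5), 0.01)
  ## wild-type reference scales the normalized value
  lv <- fishLevel(f$target, f$control, roi, bgs, wtReferenceMean = 1.5)
  expect_equal(lv$normalized, lv$ratio / 1.5)
  ## offset invariance: shifting both channels and backgrounds cancels
  f2t <- f$target + 31; f2c <- f$control + 31
  expect_equal(fishLevel(f2t, f2c, roi, bgs)$ratio,
               fishLevel(f$target, f$control, roi, bgs)$ratio)
  ## nonpositive control after subtraction errors with diagnostics
  dark <- matrix(0, 96, 96)
  bright <- matrix(100, 96, 96); bright[roi] <- 0
  expect_error(fishLevel(f$target, bright, roi, bgs), "control")
})

test_that("FISH ratio recovery holds across ratios under noise", {
  bgs <- list(roiSquare(96, 96, 2:7, 2:7), roiSquare(96, 96, 2:7, 88:93),
              roiSquare(96, 96, 88:93, 2:7))
  for (ratio in c(0.5, 2)) {
    rec <- vapply(1:5, function(i) {
      f <- renderFishField(FishFieldParams(targetMean = 40 * ratio,
                                           controlMean = 40),
                           seed = 100 * ratio + i, noise = TRUE)
      fishLevel(f$target, f$control, f$germlineMask, bgs)$ratio
    }, 0)
    expect_lt(abs(mean(rec) - ratio) / ratio, 0.05)
  }
})

test_that("condensate fraction recovers partitions and flags bad input", {
  o <- renderOocyteScene(2e5, 0.3, nFoci = 5, autofluorPerVolume = 4,
                         seed = 4)
  res <- condensateFraction(o$stack, o$oocyteMask, o$fociLabels,
                            autofluorPerVolume = 4,
                            voxelVolume = o$truth$voxelVolume)
  expect_lt(abs(res$fraction - 0.3), 0.02)
  expect_identical(res$flag, "ok")
  ## all-in-foci and arithmetic example
  stack <- array(0, c(4, 4, 2)); roi <- array(TRUE, c(4, 4, 2))
  foci <- array(0L, c(4, 4, 2)); foci[1:2, 1, 1] <- 1L
  stack[1:2, 1, 1] <- 15; stack[3, 3, 2] <- 70
  res <- condensateFraction(stack, roi, foci, 0, voxelVolume = 1)
  expect_identical(res$fraction, 0.3)
  ## over-subtraction errors; mild out-of-range warns, unclamped
  expect_error(condensateFraction(stack, roi, foci, autofluorPerVolume = 10,
                                  voxelVolume = 1), "nonpositive")
  expect_warning(
    bad <- condensateFraction(stack, roi, foci, autofluorPerVolume = 2.5,
                              voxelVolume = 1), "unclamped")
  expect_gt(bad$fraction, 1)
  expect_error(condensateFraction(stack, array(FALSE, c(4, 4, 2)), foci, 0,
                                  1), "inside")
})

test_that("group comparison uses Welch t / ANOVA with 95% CIs", {
  set.seed(12)
  same <- rnorm(40)
  p <- compareGroups(c(same, same), rep(c("a", "b"), each = 40))
  expect_identical(p$test, "welch-t")
  expect_gt(p$p.value, 0.5)
  ## large separation: delta = 10 sigma, n = 20
  x <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  sep <- compareGroups(x, rep(c("a", "b"), each = 20))
  expect_lt(sep$p.value, 1e-4)
  ## constant group has zero-width CI
  ci <- compareGroups(c(rep(5, 4), rnorm(4)),
                      rep(c("k", "r"), each = 4))$summary
  expect_identical(ci$ciLow[ci$group == "k"], ci$ciHigh[ci$group == "k"])
  ## three groups -> ANOVA
  three <- compareGroups(rnorm(30), rep(letters[1:3], each = 10))
  expect_identical(three$test, "anova")
  expect_error(compareGroups(1:5, c("a", "a", "a", "a", "b")), "two values")
})
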