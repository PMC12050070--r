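env <- EnvelopeModel(radius = 2.5, shellThickness = 0.1)

test_that("pore sampling respects counts, labels, and the envelope shell", {
  pp <- samplePorePositions(env, ClusterProcessParams(nPores = 0), seed = 1)
  expect_identical(nrow(pp$points), 0L)

  pp <- samplePorePositions(env,
    ClusterProcessParams(nPores = 300, nParents = 5,
                         offspringConcentration = 15,
                         uniformFraction = 0.2), seed = 7)
  expect_identical(nrow(pp$points), 300L)
  expect_identical(sum(pp$labels == 0L), 60L)  # round(0.2 * 300) uniform
  expect_true(all(pp$labels %in% 0:5))
  r <- sqrt(rowSums(sweep(pp$points, 2, env@center)^2))
  expect_true(all(abs(r - 2.5) <= 0.05 + 1e-12))
})

test_that("zero concentration reduces to uniform sphere sampling", {
  pp <- samplePorePositions(env,
    ClusterProcessParams(nPores = 1000, offspringConcentration = 0),
    seed = 11)
  expect_true(all(pp$labels == 0L))
  dirs <- sweep(pp$points, 2, env@center) / 2.5
  ## resultant of 1000 uniform unit vectors is ~Rayleigh; norm < 0.1 at n=1000
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 0.1)
})

test_that("uniform-limit nearest-neighbor spacing matches a Monte-Carlo oracle", {
  nnMean <- function(dirs) {
    g <- dirs %*% t(dirs)
    diag(g) <- -Inf
    mean(acos(pmin(1, apply(g, 1, max))))
  }
  pp <- samplePorePositions(env,
    ClusterProcessParams(nPores = 1000, offspringConcentration = 0),
    seed = 3)
  raw <- sweep(pp$points, 2, env@center)
  got <- nnMean(raw / sqrt(rowSums(raw^2)))  # unit directions
  ## oracle: direct uniform sphere draws, same statistic
  set.seed(99)
  z <- runif(1000, -1, 1); phi <- runif(1000, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  ref <- nnMean(cbind(s * cos(phi), s * sin(phi), z))
  expect_lt(abs(got - ref) / ref, 0.05)
})

test_that("high concentration confines offspring to the predicted cap", {
  kappa <- 1000
  n <- 400
  pp <- samplePorePositions(env,
    ClusterProcessParams(nPores = n, nParents = 1,
                         offspringConcentration = kappa,
                         uniformFraction = 0), seed = 5)
  raw <- sweep(pp$points, 2, env@center)
  dirs <- raw / sqrt(rowSums(raw^2))
  angToParent <- acos(pmin(1, dirs %*% pp$parents[1, ]))
  ## closed-form angular CDF of the kernel: all n draws should sit inside
  ## the cap whose tail mass is 1/(100 n), and the median angle should
  ## match the analytic median
  expect_lt(max(angToParent), vmfAngleQuantile(1 - 1 / (100 * n), kappa))
  expect_lt(abs(median(angToParent) - vmfAngleQuantile(0.5, kappa)) /
              vmfAngleQuantile(0.5, kappa), 0.1)
  ## and the whole cluster is confined to one small cap, far below the
  ## hemisphere scale
  g <- dirs %*% t(dirs)
  maxPair <- max(acos(pmin(1, pmax(-1, g[upper.tri(g)]))))
  expect_lt(maxPair, 2 * vmfAngleQuantile(1 - 1 / (100 * n), kappa))
})

test_that("invalid cluster-process parameters are rejected", {
  expect_error(ClusterProcessParams(offspringConcentration = 5, nParents = 0),
               "nParents")
  expect_error(ClusterProcessParams(uniformFraction = 1.5), "uniformFraction")
})

test_that("granule placement covers the requested fraction of clusters", {
  centers <- runifSphereFixture(10, seed = 2)
  expect_identical(nrow(placeGranules(centers, GranuleParams(coverageFraction = 0),
                                      seed = 1)), 0L)
  caps <- placeGranules(centers,
                        GranuleParams(coverageFraction = 1, capOffsetJitter = 0),
                        seed = 1)
  expect_identical(nrow(caps), 10L)
  ## zero jitter: exactly concentric with the clusters
  for (i in seq_len(10))
    expect_equal(unname(caps[i, 1:3]),
                 unname(centers[attr(caps, "coveredClusters")[i], ]),
                 tolerance = 1e-12)
  half <- placeGranules(centers, GranuleParams(coverageFraction = 0.5), seed = 4)
  expect_identical(nrow(half), 5L)
  expect_identical(anyDuplicated(attr(half, "coveredClusters")), 0L)
})

test_that("noise-free rendering conserves per-object photon budgets", {
  opt <- OpticsParams(backgroundLevel = 5, readNoiseSD = 0)
  ## empty scene: constant background
  st <- renderStack(matrix(numeric(), 0, 3), matrix(numeric(), 0, 4),
                    envCentered(opt), opt, shotNoise = FALSE,
                    readNoise = FALSE)
  expect_true(all(st == 5))

  ## one punctum: integrated signal above background = photon budget
  e <- envCentered(opt)
  p <- matrix(e@center, 1, 3)
  st <- renderStack(p, matrix(numeric(), 0, 4), e, opt,
                    shotNoise = FALSE, readNoise = FALSE)
  d <- dim(st)
  got <- sum(st[, , , 1]) - 5 * prod(d[1:3])
  expect_lt(abs(got - opt@photonsPerPunctum) / opt@photonsPerPunctum, 0.01)

  ## full scene: n_pores x budget and n_caps x cap budget
  sc <- simulateScene(seed = 2, shotNoise = FALSE, readNoise = FALSE)
  tr <- sceneTruth(sc)
  d <- dim(sceneStack(sc))
  bg <- tr$optics$backgroundLevel * prod(d[1:3])
  expP <- tr$clusterParams$nPores * tr$optics$photonsPerPunctum
  expG <- nrow(granuleCaps(sc)) * tr$granuleParams$intensityScale
  expect_lt(abs(sum(sceneStack(sc)[, , , 1]) - bg - expP) / expP, 0.01)
  expect_lt(abs(sum(sceneStack(sc)[, , , 2]) - bg - expG) / expG, 0.01)
})

test_that("rendering rejects geometry outside the stack bounds", {
  opt <- OpticsParams()
  e <- envCentered(opt)
  far <- matrix(c(1e3, 1e3, 1e3), 1, 3)
  expect_error(renderStack(far, matrix(numeric(), 0, 4), e, opt),
               "bounds")
})

test_that("every generator is bit-deterministic under a fixed seed", {
  a <- simulateScene(seed = 42); b <- simulateScene(seed = 42)
  expect_identical(sceneStack(a), sceneStack(b))
  expect_identical(porePoints(a), porePoints(b))
  p1 <- sampleEmPositions(50, 2, seed = 9)
  p2 <- sampleEmPositions(50, 2, seed = 9)
  expect_identical(porePositions(p1), porePositions(p2))
  f1 <- renderFishField(FishFieldParams(), seed = 13)
  f2 <- renderFishField(FishFieldParams(), seed = 13)
  expect_identical(f1$target, f2$target)
  o1 <- renderOocyteScene(1e5, 0.3, seed = 21)
  o2 <- renderOocyteScene(1e5, 0.3, seed = 21)
  expect_identical(o1$stack, o2$stack)
})

test_that("EM position sampling follows the requested process", {
  expect_error(sampleEmPositions(10, -1), "rate")
  expect_identical(length(porePositions(sampleEmPositions(10, 0, seed = 1))),
                   0L)
  prof <- sampleEmPositions(2000, 1, seed = 8)
  gaps <- diff(porePositions(prof))
  expect_lt(abs(mean(gaps) - 1), 0.05)  # exponential gaps, mean 1/rate
  ## clustered mode concentrates gaps near zero
  cl <- sampleEmPositions(100, 2, clustering = list(nParents = 5,
                                                    spread = 0.01),
                          seed = 8)
  expect_gt(mean(diff(porePositions(cl)) < 0.05), 0.5)
})

test_that("FISH fields record their truth ratio and share background", {
  expect_error(FishFieldParams(controlMean = 0), "controlMean")
  f <- renderFishField(FishFieldParams(targetMean = 100, controlMean = 50,
                                       backgroundMean = 7), seed = 1,
                       noise = FALSE)
  expect_identical(f$truth$ratio, 2)
  g <- f$germlineMask
  expect_true(all((f$target[g] - 7) / (f$control[g] - 7) == 2))
  ## outside the germline both channels are pure shared background
  expect_true(all(f$target[!g] == 7) && all(f$control[!g] == 7))
})

test_that("oocyte scenes partition signal as requested", {
  expect_error(renderOocyteScene(1e5, 0.5, nFoci = 0), "nFoci")
  o <- renderOocyteScene(1e5, 0, nFoci = 0, seed = 1)
  expect_identical(max(o$fociLabels), 0L)
  o <- renderOocyteScene(1e5, 1, nFoci = 4, seed = 2)
  expect_gt(sum(o$stack[o$fociLabels > 0]) / sum(o$stack), 0.99)
  o <- renderOocyteScene(1e5, 0.3, nFoci = 5, autofluorPerVolume = 0,
                         seed = 3)
  expect_lt(abs(sum(o$stack[o$fociLabels > 0]) / sum(o$stack) - 0.3), 0.01)
})

test_that("scene truth round-trips losslessly through serialization", {
  sc <- simulateScene(seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  writeTruth(sceneTruth(sc), path)
  back <- readTruth(path)
  ## JSON represents whole numbers without a type marker; values must
  ## round-trip exactly, integer/double class aside
  expect_equal(back$seed, sceneTruth(sc)$seed)
  expect_identical(back$optics$voxelSizeXY,
                   sceneTruth(sc)$optics$voxelSizeXY)
  expect_equal(back$clusterParams$offspringConcentration,
               sceneTruth(sc)$clusterParams$offspringConcentration)
  expect_identical(as.integer(back$coveredClusters),
                   as.integer(sceneTruth(sc)$coveredClusters))
})
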