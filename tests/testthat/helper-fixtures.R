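# Shared fixtures built in code.

# Uniform unit directions (fixture-grade; independent of package internals).
runifSphereFixture <- function(n, seed) {
  set.seed(seed)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

# Envelope centered in the field rendered for the given optics.
envCentered <- function(optics, radius = 2.5, shellThickness = 0.1) {
  e0 <- EnvelopeModel(radius = radius, shellThickness = shellThickness)
  g <- poreQuant:::stackGeometry(e0, optics)
  EnvelopeModel(center = c(g$nx * g$vxy, g$ny * g$vxy, g$nz * g$vz) / 2,
                radius = radius, shellThickness = shellThickness)
}

# A face-on test scene: clusters placed at prescribed directions tilted
# toward +z so the projection resolves them individually.
faceScene <- function(nClusters = 3, kappa = 400, poresPerCluster = 25,
                      coverage = 1, seed = 1,
                      optics = OpticsParams(backgroundLevel = 10,
                                            readNoiseSD = 0)) {
  e <- envCentered(optics)
  set.seed(seed)
  phis <- seq(0, 2 * pi, length.out = nClusters + 1L)[seq_len(nClusters)]
  tilt <- 0.55
  dirs <- cbind(sin(tilt) * cos(phis), sin(tilt) * sin(phis),
                rep(cos(tilt), nClusters))
  pts <- NULL; labs <- integer()
  for (i in seq_len(nClusters)) {
    d <- poreQuant:::rvmf(poresPerCluster, dirs[i, ], kappa)
    pts <- rbind(pts, sweep(d * e@radius, 2, e@center, "+"))
    labs <- c(labs, rep(i, poresPerCluster))
  }
  caps <- placeGranules(dirs, GranuleParams(coverageFraction = coverage,
                                            capOffsetJitter = 0),
                        seed = seed)
  stack <- renderStack(pts, caps, e, optics, seed = seed,
                       shotNoise = TRUE, readNoise = FALSE)
  list(points = pts, labels = labs, dirs = dirs, caps = caps,
       envelope = e, optics = optics, stack = stack)
}

# Random small binary-mask pair for overlap property tests.
randomMaskPair <- function(seed, nr = 12, nc = 15) {
  set.seed(seed)
  a <- matrix(runif(nr * nc) < runif(1, 0.2, 0.8), nr, nc)
  if (!any(a)) a[1, 1] <- TRUE
  b <- matrix(runif(nr * nc) < runif(1, 0.1, 0.9), nr, nc)
  list(
    ref = new("BinaryMask", pixels = array(a, dim(a)), pixelSizeXY = 0.1,
              thresholdMethod = "fixed", thresholdValue = 0.5),
    sel = new("BinaryMask", pixels = array(b, dim(b)), pixelSizeXY = 0.1,
              thresholdMethod = "fixed", thresholdValue = 0.5))
}
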