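#' @include AllClasses.R
NULL

## Internal geometry helpers ------------------------------------------------

## Uniform directions on the unit sphere.
runifSphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

## von Mises-Fisher directions around unit mean mu with concentration kappa.
## Inverse-CDF sampling of the cosine w, then a uniform azimuth in the
## tangent plane (Fisher distribution on S2).
rvmf <- function(n, mu, kappa) {
  if (kappa == 0) return(runifSphere(n))
  u <- stats::runif(n)
  ## w = cos(angle to mu); closed-form inverse CDF for S2
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(phi), s * sin(phi), w)
  ## world = a e1 + b e2 + w mu, with (e1, e2, mu) the rows of the basis
  local %*% rotationToZ(mu)
}

## Rotation matrix R with R %*% z = mu (rows give basis: e1, e2, mu).
rotationToZ <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  rbind(e1, e2, mu)
}

## Rotate unit vector dir away from itself by angle theta in a uniformly
## random tangent direction.
jitterDirection <- function(dir, theta) {
  if (theta == 0) return(dir)
  basis <- rotationToZ(dir)
  phi <- stats::runif(1, 0, 2 * pi)
  sin(theta) * cos(phi) * basis[1, ] +
    sin(theta) * sin(phi) * basis[2, ] + cos(theta) * dir
}

## ---------------------------------------------------------------------------
## Pore placement
## ---------------------------------------------------------------------------

#' Sample ground-truth pore positions on a nuclear envelope
#'
#' Places `nPores` pore centers on the envelope shell by a Matern-style
#' parent/offspring process: parent directions are uniform on the sphere,
#' offspring follow a von Mises-Fisher kernel of concentration
#' `offspringConcentration` around a uniformly chosen parent. A fraction
#' `uniformFraction` of pores is placed uniformly over the whole sphere
#' (cluster label 0); with concentration 0 the process degenerates to
#' fully uniform sampling.
#'
#' @param envelope an [EnvelopeModel-class].
#' @param params a [ClusterProcessParams-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `points` (n x 3 matrix of positions, micron),
#'   `labels` (integer cluster label per point; 0 = uniform/dispersed) and
#'   `parents` (nParents x 3 matrix of unit parent directions, or
#'   a 0-row matrix in the uniform limit).
#' @examples
#' env <- EnvelopeModel(radius = 2.5)
#' pp <- samplePorePositions(env, ClusterProcessParams(nPores = 100), seed = 1)
#' table(pp$labels)
#' @export
samplePorePositions <- function(envelope, params, seed = NULL) {
  stopifnot(is(envelope, "EnvelopeModel"), is(params, "ClusterProcessParams"))
  validObject(envelope); validObject(params)
  if (params@offspringConcentration > 0 && params@nParents < 1L)
    stop("offspringConcentration > 0 requires at least one parent")
  doSample <- function() {
    n <- params@nPores
    kappa <- params@offspringConcentration
    if (n == 0L)
      return(list(points = matrix(numeric(), 0L, 3L,
                                  dimnames = list(NULL, c("x", "y", "z"))),
                  labels = integer(),
                  parents = matrix(numeric(), 0L, 3L)))
    if (kappa == 0) {
      dirs <- runifSphere(n)
      labels <- rep(0L, n)
      parents <- matrix(numeric(), 0L, 3L)
    } else {
      parents <- runifSphere(params@nParents)
      nU <- round(params@uniformFraction * n)
      nC <- n - nU
      assign <- if (nC > 0L)
        sample.int(params@nParents, nC, replace = TRUE) else integer()
      dirsC <- matrix(0, nC, 3L)
      for (p in seq_len(params@nParents)) {
        idx <- which(assign == p)
        if (length(idx))
          dirsC[idx, ] <- rvmf(length(idx), parents[p, ], kappa)
      }
      dirsU <- runifSphere(nU)
      dirs <- rbind(dirsC, dirsU)
      labels <- c(assign, rep(0L, nU))
    }
    t2 <- envelope@shellThickness / 2
    r <- envelope@radius +
      if (t2 > 0) stats::runif(n, -t2, t2) else rep(0, n)
    pts <- dirs * r
    pts <- sweep(pts, 2L, envelope@center, "+")
    colnames(pts) <- c("x", "y", "z")
    list(points = pts, labels = as.integer(labels), parents = parents)
  }
  if (is.null(seed)) doSample() else withr::with_seed(seed, doSample())
}

#' Place granule caps over pore clusters
#'
#' Chooses `round(coverageFraction * nClusters)` distinct clusters and
#' centers one spherical-cap granule on each, perturbing the cap center by
#' an angular offset drawn from a half-normal distribution with standard
#' deviation `capOffsetJitter` (imperfect registration between clusters
#' and granules). With zero jitter, caps are exactly concentric with their
#' clusters.
#'
#' @param clusterCenters m x 3 matrix of unit cluster-center directions.
#' @param params a [GranuleParams-class].
#' @param seed integer seed.
#' @return k x 4 matrix with columns `x, y, z` (unit cap direction) and
#'   `angularRadius` (radians); attribute `coveredClusters` holds the row
#'   indices of the clusters that received a cap.
#' @export
placeGranules <- function(clusterCenters, params, seed = NULL) {
  stopifnot(is(params, "GranuleParams"))
  validObject(params)
  clusterCenters <- as.matrix(clusterCenters)
  m <- nrow(clusterCenters)
  doPlace <- function() {
    k <- round(params@coverageFraction * m)
    chosen <- if (k > 0L) sort(sample.int(m, k)) else integer()
    caps <- matrix(numeric(), 0L, 4L)
    if (k > 0L) {
      caps <- t(vapply(chosen, function(i) {
        d <- clusterCenters[i, ]
        d <- d / sqrt(sum(d^2))
        theta <- abs(stats::rnorm(1, 0, params@capOffsetJitter))
        c(jitterDirection(d, theta), params@capAngularRadius)
      }, numeric(4)))
    }
    colnames(caps) <- c("x", "y", "z", "angularRadius")
    attr(caps, "coveredClusters") <- chosen
    caps
  }
  if (is.null(seed)) doPlace() else withr::with_seed(seed, doPlace())
}

## ---------------------------------------------------------------------------
## Image formation
## ---------------------------------------------------------------------------

## Per-axis voxel-integrated Gaussian mass: P(center mu, sd sigma falls in
## voxel i) for voxels 1..n of size h. Exact via the normal CDF.
axisMass <- function(n, h, mu, sigma) {
  edges <- (0:n) * h
  diff(stats::pnorm(edges, mean = mu, sd = sigma))
}

## Zero-padded shift of a 3-D array along one dimension.
shift3 <- function(a, off, dim) {
  if (off == 0L) return(a)
  d <- base::dim(a)
  out <- array(0, d)
  n <- d[dim]
  src <- seq_len(n - abs(off))
  if (off > 0L) {
    to <- src + off
  } else {
    to <- src
    src <- src - off
  }
  ix <- rep(list(quote(expr = )), 3L)
  ixs <- ix; ixs[[dim]] <- src
  ixt <- ix; ixt[[dim]] <- to
  out <- do.call(`[<-`, c(list(out), ixt,
                          list(do.call(`[`, c(list(a), ixs, drop = FALSE)))))
  out
}

## Separable Gaussian blur of a 3-D array with voxel-integrated kernels.
gaussBlur3 <- function(a, sigmaXY, sigmaZ, vxy, vz) {
  blur1 <- function(a, sigma, h, dim) {
    if (sigma <= 0) return(a)
    hw <- max(1L, ceiling(5 * sigma / h))
    offs <- (-hw):hw
    k <- stats::pnorm((offs + 0.5) * h, sd = sigma) -
         stats::pnorm((offs - 0.5) * h, sd = sigma)
    k <- k / sum(k)
    out <- array(0, base::dim(a))
    for (i in seq_along(offs)) out <- out + k[i] * shift3(a, offs[i], dim)
    out
  }
  a <- blur1(a, sigmaXY, vxy, 1L)
  a <- blur1(a, sigmaXY, vxy, 2L)
  blur1(a, sigmaZ, vz, 3L)
}

## Stack geometry derived from optics + envelope.
stackGeometry <- function(envelope, optics) {
  vxy <- optics@voxelSizeXY; vz <- optics@voxelSizeZ
  nz <- max(1L, round(optics@stackDepth / vz))
  fw <- optics@fieldWidth
  if (is.na(fw))
    fw <- 2 * (envelope@radius + envelope@shellThickness / 2 + 0.5 +
               4 * optics@psfSigmaXY)
  nxy <- ceiling(fw / vxy)
  list(ny = nxy, nx = nxy, nz = nz, vxy = vxy, vz = vz)
}

#' Render a two-channel voxel stack from scene geometry
#'
#' Image formation: each pore punctum contributes an anisotropic Gaussian
#' PSF integrated exactly over voxels (so its photon budget is conserved
#' for puncta away from the stack border); granule caps are rendered as
#' solid spherical-cap shells abutting the envelope, normalized to
#' `intensityScale` photons per cap, then blurred with the same PSF.
#' Optional Poisson shot noise acts on signal plus background; optional
#' Gaussian read noise is additive.
#'
#' @param porePoints n x 3 matrix of pore positions (micron).
#' @param granuleCaps k x 4 matrix as from [placeGranules()] (may have 0
#'   rows).
#' @param envelope the [EnvelopeModel-class] the caps sit on.
#' @param optics an [OpticsParams-class].
#' @param granules a [GranuleParams-class] (for cap thickness and photon
#'   budget).
#' @param seed integer seed for the noise draws.
#' @param shotNoise,readNoise logical; disable for noise-free oracle
#'   images.
#' @return 4-D array (y, x, z, channel); channel 1 = pores, channel 2 =
#'   granules.
#' @export
renderStack <- function(porePoints, granuleCaps, envelope, optics,
                        granules = GranuleParams(), seed = NULL,
                        shotNoise = TRUE, readNoise = TRUE) {
  stopifnot(is(envelope, "EnvelopeModel"), is(optics, "OpticsParams"))
  g <- stackGeometry(envelope, optics)
  porePoints <- as.matrix(porePoints)
  extentX <- g$nx * g$vxy; extentY <- g$ny * g$vxy; extentZ <- g$nz * g$vz
  if (nrow(porePoints)) {
    mxy <- 4 * optics@psfSigmaXY; mz <- 4 * optics@psfSigmaZ
    inb <- porePoints[, 1] >= mxy & porePoints[, 1] <= extentX - mxy &
           porePoints[, 2] >= mxy & porePoints[, 2] <= extentY - mxy &
           porePoints[, 3] >= mz  & porePoints[, 3] <= extentZ - mz
    if (!all(inb))
      stop("scene geometry exceeds stack bounds: ", sum(!inb),
           " pore(s) closer than 4 sigma to the border")
  }
  pore <- array(0, c(g$ny, g$nx, g$nz))
  if (nrow(porePoints)) {
    hwXY <- ceiling(5 * optics@psfSigmaXY / g$vxy)
    hwZ <- max(1L, ceiling(5 * optics@psfSigmaZ / g$vz))
    for (i in seq_len(nrow(porePoints))) {
      px <- porePoints[i, 1]; py <- porePoints[i, 2]; pz <- porePoints[i, 3]
      cx <- ceiling(px / g$vxy); cy <- ceiling(py / g$vxy)
      cz <- ceiling(pz / g$vz)
      xi <- max(1L, cx - hwXY):min(g$nx, cx + hwXY)
      yi <- max(1L, cy - hwXY):min(g$ny, cy + hwXY)
      zi <- max(1L, cz - hwZ):min(g$nz, cz + hwZ)
      mx <- diff(stats::pnorm(c(xi[1] - 1L, xi) * g$vxy, px,
                              optics@psfSigmaXY))
      my <- diff(stats::pnorm(c(yi[1] - 1L, yi) * g$vxy, py,
                              optics@psfSigmaXY))
      mz2 <- diff(stats::pnorm(c(zi[1] - 1L, zi) * g$vz, pz,
                               optics@psfSigmaZ))
      blob <- (my %o% mx) %o% mz2 * optics@photonsPerPunctum
      pore[yi, xi, zi] <- pore[yi, xi, zi] + blob
    }
  }
  gran <- array(0, c(g$ny, g$nx, g$nz))
  granuleCaps <- as.matrix(granuleCaps)
  if (nrow(granuleCaps)) {
    xc <- ((1:g$nx) - 0.5) * g$vxy
    yc <- ((1:g$ny) - 0.5) * g$vxy
    zc <- ((1:g$nz) - 0.5) * g$vz
    X <- array(rep(xc, each = g$ny), c(g$ny, g$nx, g$nz))
    Y <- array(rep(yc, times = g$nx * g$nz), c(g$ny, g$nx, g$nz))
    Z <- array(rep(zc, each = g$ny * g$nx), c(g$ny, g$nx, g$nz))
    dx <- X - envelope@center[1]
    dy <- Y - envelope@center[2]
    dz <- Z - envelope@center[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    shell <- r >= envelope@radius & r <= envelope@radius + granules@capThickness
    for (i in seq_len(nrow(granuleCaps))) {
      d <- granuleCaps[i, 1:3]
      cosang <- (dx * d[1] + dy * d[2] + dz * d[3]) / pmax(r, 1e-12)
      inCap <- shell & cosang >= cos(granuleCaps[i, 4])
      nvox <- sum(inCap)
      if (nvox > 0)
        gran[inCap] <- gran[inCap] + granules@intensityScale / nvox
    }
    gran <- gaussBlur3(gran, optics@psfSigmaXY, optics@psfSigmaZ,
                       g$vxy, g$vz)
  }
  addNoise <- function(ch) {
    ch <- ch + optics@backgroundLevel
    if (shotNoise)
      ch <- array(stats::rpois(length(ch), ch), base::dim(ch))
    if (readNoise && optics@readNoiseSD > 0)
      ch <- ch + stats::rnorm(length(ch), 0, optics@readNoiseSD)
    pmax(ch, 0)
  }
  assemble <- function() {
    out <- array(0, c(g$ny, g$nx, g$nz, 2L))
    out[, , , 1L] <- addNoise(pore)
    out[, , , 2L] <- addNoise(gran)
    out
  }
  if (is.null(seed)) assemble() else withr::with_seed(seed, assemble())
}

#' Simulate a complete synthetic nucleus scene
#'
#' Convenience wrapper: builds an envelope centered in the rendered field,
#' samples pore positions, places granule caps over the cluster centers,
#' renders the two-channel stack, and packs everything with its ground
#' truth into a [SyntheticScene-class].
#'
#' @param clusterParams a [ClusterProcessParams-class].
#' @param granuleParams a [GranuleParams-class].
#' @param optics an [OpticsParams-class].
#' @param radius envelope radius (micron).
#' @param shellThickness envelope shell thickness (micron).
#' @param seed integer seed driving all random draws.
#' @param shotNoise,readNoise noise switches passed to [renderStack()].
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- simulateScene(seed = 1)
#' sc
#' @export
simulateScene <- function(clusterParams = ClusterProcessParams(),
                          granuleParams = GranuleParams(),
                          optics = OpticsParams(), radius = 2.5,
                          shellThickness = 0.1, seed = 1,
                          shotNoise = TRUE, readNoise = TRUE) {
  env0 <- EnvelopeModel(center = c(0, 0, 0), radius = radius,
                        shellThickness = shellThickness)
  g <- stackGeometry(env0, optics)
  center <- c(g$nx * g$vxy / 2, g$ny * g$vxy / 2, g$nz * g$vz / 2)
  env <- EnvelopeModel(center = center, radius = radius,
                       shellThickness = shellThickness)
  pp <- samplePorePositions(env, clusterParams, seed = seed)
  ## cluster centers: mean direction per non-sentinel label
  labs <- sort(unique(pp$labels[pp$labels > 0L]))
  centers <- matrix(numeric(), 0L, 3L)
  if (length(labs)) {
    centers <- t(vapply(labs, function(l) {
      d <- colMeans(sweep(pp$points[pp$labels == l, , drop = FALSE],
                          2L, center))
      d / sqrt(sum(d^2))
    }, numeric(3)))
  }
  caps <- placeGranules(centers, granuleParams, seed = seed + 1L)
  covered <- labs[attr(caps, "coveredClusters")]
  stack <- renderStack(pp$points, caps, env, optics,
                       granules = granuleParams, seed = seed + 2L,
                       shotNoise = shotNoise, readNoise = readNoise)
  truth <- list(
    seed = seed, radius = radius, shellThickness = shellThickness,
    clusterParams = list(nPores = clusterParams@nPores,
                         nParents = clusterParams@nParents,
                         offspringConcentration =
                           clusterParams@offspringConcentration,
                         uniformFraction = clusterParams@uniformFraction),
    granuleParams = list(coverageFraction = granuleParams@coverageFraction,
                         capAngularRadius = granuleParams@capAngularRadius,
                         capOffsetJitter = granuleParams@capOffsetJitter,
                         intensityScale = granuleParams@intensityScale,
                         capThickness = granuleParams@capThickness),
    optics = list(voxelSizeXY = optics@voxelSizeXY,
                  voxelSizeZ = optics@voxelSizeZ,
                  psfSigmaXY = optics@psfSigmaXY,
                  psfSigmaZ = optics@psfSigmaZ,
                  backgroundLevel = optics@backgroundLevel,
                  photonsPerPunctum = optics@photonsPerPunctum,
                  readNoiseSD = optics@readNoiseSD,
                  stackDepth = optics@stackDepth,
                  fieldWidth = optics@fieldWidth),
    clusterIds = labs, coveredClusters = covered,
    shotNoise = shotNoise, readNoise = readNoise)
  new("SyntheticScene", porePoints = pp$points, clusterLabels = pp$labels,
      granuleCaps = caps, stack = stack, envelope = env, truth = truth)
}

## ---------------------------------------------------------------------------
## EM profiles
## ---------------------------------------------------------------------------

#' Sample 1-D pore positions along an EM cross-section
#'
#' Homogeneous mode draws a 1-D Poisson process of the given rate over
#' `[0, length]`. Clustered mode places parents uniformly and scatters
#' pores as Gaussians of standard deviation `spread` around them
#' (out-of-range draws are resampled).
#'
#' @param length contour length (micron, > 0).
#' @param rate expected pores per micron (>= 0).
#' @param clustering `NULL` for homogeneous, or `list(nParents=, spread=)`.
#' @param seed integer seed.
#' @param poreDiameter diameter convention recorded on the profile (nm).
#' @return a [PoreProfile-class].
#' @export
sampleEmPositions <- function(length, rate, clustering = NULL, seed = NULL,
                              poreDiameter = 110) {
  if (length <= 0) stop("length must be > 0")
  if (rate < 0) stop("rate must be >= 0")
  doSample <- function() {
    n <- stats::rpois(1, rate * length)
    if (n == 0L) return(PoreProfile(numeric(), poreDiameter))
    if (is.null(clustering)) {
      pos <- sort(stats::runif(n, 0, length))
    } else {
      np <- as.integer(clustering$nParents)
      spread <- as.numeric(clustering$spread)
      if (np < 1L) stop("clustered mode requires nParents >= 1")
      parents <- stats::runif(np, 0, length)
      assign <- sample.int(np, n, replace = TRUE)
      pos <- stats::rnorm(n, parents[assign], spread)
      bad <- which(pos < 0 | pos > length)
      while (length(bad)) {
        pos[bad] <- stats::rnorm(length(bad), parents[assign[bad]], spread)
        bad <- bad[pos[bad] < 0 | pos[bad] > length]
      }
      pos <- sort(pos)
    }
    PoreProfile(pos, poreDiameter)
  }
  if (is.null(seed)) doSample() else withr::with_seed(seed, doSample())
}

## ---------------------------------------------------------------------------
## FISH fields and oocyte scenes
## ---------------------------------------------------------------------------

#' Render a synthetic two-channel FISH field
#'
#' Emulates a target-transcript channel and a control-transcript channel
#' over a germline region occupying the center of the field; outside the
#' germline only the shared constant background remains, which is where
#' background-measurement regions belong. Optional granule disks (inside
#' the germline) boost the target channel only. Poisson noise is
#' optional.
#'
#' @param params a [FishFieldParams-class].
#' @param seed integer seed.
#' @param noise logical; apply Poisson shot noise per pixel.
#' @return list with `target` and `control` intensity matrices,
#'   `germlineMask` and `granuleMask` (logical), and `truth` (list with
#'   `ratio` = targetMean / controlMean and the generator parameters).
#' @export
renderFishField <- function(params, seed = NULL, noise = TRUE) {
  stopifnot(is(params, "FishFieldParams"))
  validObject(params)
  doRender <- function() {
    nr <- params@fieldShape[1]; nc <- params@fieldShape[2]
    ## germline: centered rectangle covering ~55% of each dimension
    rowIn <- seq_len(nr) >= ceiling(nr * 0.225) &
             seq_len(nr) <= floor(nr * 0.775)
    colIn <- seq_len(nc) >= ceiling(nc * 0.225) &
             seq_len(nc) <= floor(nc * 0.775)
    germ <- outer(rowIn, colIn, "&")
    boost <- matrix(1, nr, nc)
    gmask <- matrix(FALSE, nr, nc)
    if (params@nGranules > 0L) {
      rad <- params@granuleRadius
      rlo <- which(rowIn)[1] + rad; rhi <- max(which(rowIn)) - rad
      clo <- which(colIn)[1] + rad; chi <- max(which(colIn)) - rad
      for (i in seq_len(params@nGranules)) {
        cy <- stats::runif(1, rlo, rhi)
        cx <- stats::runif(1, clo, chi)
        d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
        gmask <- gmask | d2 <= rad^2
      }
      boost[gmask] <- params@granuleBoost
    }
    target <- params@backgroundMean + params@targetMean * boost * germ
    control <- params@backgroundMean + params@controlMean * germ
    if (noise) {
      target <- matrix(stats::rpois(nr * nc, target), nr, nc)
      control <- matrix(stats::rpois(nr * nc, control), nr, nc)
    }
    list(target = target, control = control, germlineMask = germ,
         granuleMask = gmask,
         truth = list(ratio = params@targetMean / params@controlMean,
                      targetMean = params@targetMean,
                      controlMean = params@controlMean,
                      backgroundMean = params@backgroundMean,
                      granuleBoost = params@granuleBoost, noise = noise))
  }
  if (is.null(seed)) doRender() else withr::with_seed(seed, doRender())
}

#' Render a synthetic oocyte stack with a known condensate fraction
#'
#' Partitions a total photon budget between cytoplasmic foci (condensate)
#' and a diffuse pool spread uniformly over the oocyte region outside the
#' foci. Foci are voxel-integrated Gaussian spots; the truth record holds
#' the foci label array, the oocyte mask and the autofluorescence
#' contribution separately.
#'
#' @param totalSignal total tagged-protein photon budget.
#' @param fractionInFoci fraction of `totalSignal` placed in foci, in
#'   [0, 1].
#' @param nFoci number of foci (> 0 whenever `fractionInFoci` > 0).
#' @param autofluorPerVolume autofluorescent background per cubic micron
#'   added inside the oocyte region.
#' @param optics an [OpticsParams-class]; `fieldWidth` must be set or is
#'   defaulted to 8 micron.
#' @param oocyteRadius radius of the spherical oocyte region (micron).
#' @param fociSigma Gaussian sigma of each focus (micron).
#' @param seed integer seed.
#' @param noise logical; Poisson noise on the final stack.
#' @return list with `stack` (3-D array), `oocyteMask` (logical array),
#'   `fociLabels` (integer array, 0 = background), and `truth`.
#' @export
renderOocyteScene <- function(totalSignal, fractionInFoci, nFoci = 5,
                              autofluorPerVolume = 0,
                              optics = OpticsParams(fieldWidth = 8),
                              oocyteRadius = 3, fociSigma = 0.15,
                              seed = NULL, noise = FALSE) {
  if (fractionInFoci < 0 || fractionInFoci > 1)
    stop("fractionInFoci must lie in [0, 1]")
  if (nFoci == 0L && fractionInFoci > 0)
    stop("fractionInFoci > 0 requires nFoci >= 1")
  fw <- if (is.na(optics@fieldWidth)) 8 else optics@fieldWidth
  vxy <- optics@voxelSizeXY; vz <- optics@voxelSizeZ
  nxy <- ceiling(fw / vxy)
  nz <- max(1L, round(optics@stackDepth / vz))
  doRender <- function() {
    xc <- ((1:nxy) - 0.5) * vxy
    zc <- ((1:nz) - 0.5) * vz
    cx <- fw / 2; cz <- nz * vz / 2
    X <- array(rep(xc, each = nxy), c(nxy, nxy, nz))
    Y <- array(rep(xc, times = nxy * nz), c(nxy, nxy, nz))
    Z <- array(rep(zc, each = nxy * nxy), c(nxy, nxy, nz))
    ## oocyte: ellipsoid flattened to the stack depth
    rz <- min(oocyteRadius, nz * vz / 2 - 2 * optics@psfSigmaZ)
    roi <- ((X - cx)^2 + (Y - cx)^2) / oocyteRadius^2 +
           (Z - cz)^2 / rz^2 <= 1
    stack <- array(0, c(nxy, nxy, nz))
    foci <- array(0L, c(nxy, nxy, nz))
    maskR <- 4 * fociSigma
    if (nFoci > 0L && fractionInFoci > 0) {
      budget <- totalSignal * fractionInFoci / nFoci
      placed <- 0L
      while (placed < nFoci) {
        px <- stats::runif(1, maskR, fw - maskR)
        py <- stats::runif(1, maskR, fw - maskR)
        pz <- stats::runif(1, maskR, nz * vz - maskR)
        if (((px - cx)^2 + (py - cx)^2) / (0.8 * oocyteRadius)^2 +
            (pz - cz)^2 / (0.8 * rz)^2 > 1) next
        placed <- placed + 1L
        hw <- ceiling(5 * fociSigma / vxy)
        hwz <- max(1L, ceiling(5 * fociSigma / vz))
        ix <- max(1L, ceiling(px / vxy) - hw):min(nxy, ceiling(px / vxy) + hw)
        iy <- max(1L, ceiling(py / vxy) - hw):min(nxy, ceiling(py / vxy) + hw)
        iz <- max(1L, ceiling(pz / vz) - hwz):min(nz, ceiling(pz / vz) + hwz)
        mx <- diff(stats::pnorm(c(ix[1] - 1L, ix) * vxy, px, fociSigma))
        my <- diff(stats::pnorm(c(iy[1] - 1L, iy) * vxy, py, fociSigma))
        mz <- diff(stats::pnorm(c(iz[1] - 1L, iz) * vz, pz, fociSigma))
        stack[iy, ix, iz] <- stack[iy, ix, iz] + (my %o% mx) %o% mz * budget
        inSpot <- (X - px)^2 + (Y - py)^2 + (Z - pz)^2 <= maskR^2
        foci[inSpot] <- placed
      }
    }
    diffuseRegion <- roi & foci == 0L
    nDiff <- sum(diffuseRegion)
    if (nDiff > 0)
      stack[diffuseRegion] <- stack[diffuseRegion] +
        totalSignal * (1 - fractionInFoci) / nDiff
    voxVol <- vxy^2 * vz
    autofluor <- autofluorPerVolume * voxVol
    stack[roi] <- stack[roi] + autofluor
    if (noise) stack <- array(stats::rpois(length(stack), stack), dim(stack))
    list(stack = stack, oocyteMask = roi, fociLabels = foci,
         truth = list(totalSignal = totalSignal,
                      fractionInFoci = fractionInFoci, nFoci = nFoci,
                      autofluorPerVolume = autofluorPerVolume,
                      autofluorTotal = autofluor * sum(roi),
                      roiVolume = sum(roi) * voxVol,
                      voxelVolume = voxVol, noise = noise))
  }
  if (is.null(seed)) doRender() else withr::with_seed(seed, doRender())
}
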