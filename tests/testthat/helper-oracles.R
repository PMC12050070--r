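# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the dumbest possible loop so they share no
# code path with the package implementation.

oracleMaxProject <- function(stack, zidx) {
  d <- dim(stack)
  out <- matrix(-Inf, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    for (k in zidx) out[i, j] <- max(out[i, j], stack[i, j, k])
  }
  out
}

oracleOverlapCount <- function(a, b) {
  n <- 0L
  for (i in seq_along(a)) if (a[i] && b[i]) n <- n + 1L
  n
}

oracleBgsubIntegratedDensity <- function(img, roi, bgs) {
  roiSum <- 0; nRoi <- 0L
  for (i in seq_along(img)) if (roi[i]) { roiSum <- roiSum + img[i]; nRoi <- nRoi + 1L }
  means <- numeric(length(bgs))
  for (j in seq_along(bgs)) {
    s <- 0; n <- 0L
    for (i in seq_along(img)) if (bgs[[j]][i]) { s <- s + img[i]; n <- n + 1L }
    means[j] <- s / n
  }
  roiSum - mean(means) * nRoi
}

oracleAreaHistogram <- function(areas, edges) {
  nb <- length(edges) - 1L
  tot <- numeric(nb); cnt <- integer(nb)
  for (a in areas) for (b in seq_len(nb)) {
    if (a >= edges[b] && a < edges[b + 1L]) {
      tot[b] <- tot[b] + a; cnt[b] <- cnt[b] + 1L
    }
  }
  list(totalArea = tot, count = cnt)
}

oracleAdjacentGaps <- function(pos) {
  pos <- sort(pos)
  g <- numeric(length(pos) - 1L)
  for (i in seq_len(length(pos) - 1L)) g[i] <- pos[i + 1L] - pos[i]
  g
}

# Exhaustive Otsu: for each candidate split of a 256-bin histogram compute
# the between-class variance from scratch and keep the best (first on ties).
oracleOtsu <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  best <- -Inf; bestK <- NA_integer_
  for (k in seq_len(nbins - 1L)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts[(k + 1L):nbins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1L):nbins] * mids[(k + 1L):nbins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestK <- k }
  }
  edges[bestK + 1L]
}

# BFS flood fill with 8-connectivity.
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# Equality of labelings up to label permutation.
sameLabeling <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  f <- which(a > 0L)
  if (!length(f)) return(TRUE)
  length(unique(paste(a[f], b[f]))) == length(unique(a[f])) &&
    length(unique(a[f])) == length(unique(b[f]))
}

# 3x3 in-bounds mean filter, loop form.
oracleSmooth <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0; n <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      y <- i + dy; x <- j + dx
      if (y >= 1 && y <= nr && x >= 1 && x <= nc) { s <- s + img[y, x]; n <- n + 1L }
    }
    out[i, j] <- s / n
  }
  out
}

# Numeric inverse CDF of the von Mises-Fisher polar angle on the sphere
# (closed form for the cosine), independent of the sampler.
vmfAngleQuantile <- function(p, kappa) {
  w <- 1 + log(1 - p * (1 - exp(-2 * kappa))) / kappa
  acos(w)
}

angularDistance <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v))))
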