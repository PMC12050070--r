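#' @include AllClasses.R
NULL

#' Center-to-center distances between adjacent pores
#'
#' Consecutive gaps along the digitized envelope contour. The default
#' counts each adjacency once (n - 1 gaps for n pores); `mode =
#' "per-pore"` emits both neighbors of every interior pore, which
#' double-counts each gap and only rescales the histogram.
#'
#' @param profile a [PoreProfile-class] or a numeric position vector.
#' @param mode `"pair"` (default) or `"per-pore"`.
#' @return numeric vector of gaps, in the profile's units.
#' @examples
#' adjacentDistances(PoreProfile(c(0, 1, 3)))  # 1 2
#' @export
adjacentDistances <- function(profile, mode = c("pair", "per-pore")) {
  mode <- match.arg(mode)
  pos <- if (is(profile, "PoreProfile")) profile@positions
         else sort(as.numeric(profile))
  if (length(pos) < 2L)
    stop("adjacent distances require at least 2 pore positions")
  g <- diff(pos)
  if (mode == "per-pore") g <- c(g, g) # each adjacency seen from both pores
  g
}

#' Histogram of adjacent-pore distances
#'
#' Counts gaps per `[edge_i, edge_{i+1})` bin; the total over bins equals
#' the number of in-range gaps.
#'
#' @param gaps numeric gaps from [adjacentDistances()].
#' @param binEdges strictly increasing bin edges.
#' @return data.frame with `binLow`, `binHigh`, `count`, `frequency`
#'   (count / total in-range count; `NaN` when empty).
#' @export
spacingHistogram <- function(gaps, binEdges) {
  binEdges <- as.numeric(binEdges)
  if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing with >= 2 edges")
  gaps <- as.numeric(gaps)
  nb <- length(binEdges) - 1L
  idx <- findInterval(gaps, binEdges)
  inRange <- idx >= 1L & idx <= nb & gaps < binEdges[nb + 1L]
  count <- as.integer(table(factor(idx[inRange], levels = seq_len(nb))))
  data.frame(binLow = binEdges[-(nb + 1L)], binHigh = binEdges[-1L],
             count = count, frequency = count / sum(count))
}
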