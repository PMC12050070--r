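#' @include AllClasses.R
NULL

#' Background-subtracted integrated density of an ROI
#'
#' Sums the intensity over the ROI and subtracts the background estimated
#' from one or more regions just outside the structure of interest,
#' scaled to the ROI's pixel count. The default background estimate is
#' the average of the per-region mean intensities ("average fluorescence
#' of N regions"); `bgMode = "pooled"` instead pools all background
#' pixels before taking the mean. The two agree for equal-size regions.
#'
#' @param img numeric matrix or array.
#' @param roiMask logical mask of the ROI (same shape as `img`).
#' @param bgMasks a single logical mask or a list of them; must be
#'   disjoint from the ROI.
#' @param bgMode `"region-mean"` (default) or `"pooled"`.
#' @return list with `integratedDensity` (raw sum), `corrected`
#'   (background-subtracted), `area` (ROI pixel count), `mean` (raw
#'   per-pixel mean), and `bgPerPixel`.
#' @examples
#' img <- matrix(10, 10, 10); img[3:4, 3:4] <- 20
#' roi <- matrix(FALSE, 10, 10); roi[3:4, 3:4] <- TRUE
#' bg <- matrix(FALSE, 10, 10); bg[8:9, 8:9] <- TRUE
#' integratedDensityBgsub(img, roi, bg)$corrected  # 40
#' @export
integratedDensityBgsub <- function(img, roiMask, bgMasks,
                                   bgMode = c("region-mean", "pooled")) {
  bgMode <- match.arg(bgMode)
  a <- as.array(img)
  roiMask <- array(as.logical(roiMask), dim(a))
  if (!is.list(bgMasks)) bgMasks <- list(bgMasks)
  bgMasks <- lapply(bgMasks, function(m) array(as.logical(m), dim(a)))
  if (!sum(roiMask)) stop("empty ROI")
  if (!length(bgMasks) || any(!vapply(bgMasks, sum, 0)))
    stop("every background region must be non-empty")
  for (m in bgMasks)
    if (any(m & roiMask)) stop("background regions must be disjoint from ROI")
  nRoi <- sum(roiMask)
  roiSum <- sum(a[roiMask])
  bgPerPixel <- if (bgMode == "pooled") {
    pool <- Reduce(`|`, bgMasks)
    sum(a[pool]) / sum(pool)
  } else {
    mean(vapply(bgMasks, function(m) sum(a[m]) / sum(m), 0))
  }
  list(integratedDensity = roiSum,
       corrected = roiSum - bgPerPixel * nRoi,
       area = nRoi, mean = roiSum / nRoi, bgPerPixel = bgPerPixel)
}

#' Germline-versus-hypodermal nucleus intensity ratios
#'
#' Normalizes the background-subtracted values of a first germline
#' nucleus and a hypodermal nucleus to a second germline nucleus measured
#' in the same plane, and also emits per-area (signal per pixel)
#' variants.
#'
#' @param germline1,germline2,hypodermal lists as returned by
#'   [integratedDensityBgsub()].
#' @return data.frame with one row per nucleus: `nucleus`, `corrected`,
#'   `normalized` (germline2 = 1), `perArea`, `perAreaNormalized`.
#' @export
nucleusPanelRatios <- function(germline1, germline2, hypodermal) {
  ref <- germline2$corrected
  if (!is.finite(ref) || ref <= 0)
    stop("reference germline nucleus has nonpositive corrected signal")
  refPA <- germline2$corrected / germline2$area
  row <- function(name, m)
    data.frame(nucleus = name, corrected = m$corrected,
               normalized = m$corrected / ref,
               perArea = m$corrected / m$area,
               perAreaNormalized = (m$corrected / m$area) / refPA)
  rbind(row("germline1", germline1), row("germline2", germline2),
        row("hypodermal", hypodermal))
}

#' FISH transcript level with control-transcript normalization
#'
#' Background-subtracts the target and control channels over the same
#' germline ROI using the average fluorescence of the background regions,
#' forms the target/control ratio, and scales by `wtReferenceMean` so the
#' wild-type group averages 1.0.
#'
#' @param targetImg,controlImg numeric matrices (same shape).
#' @param germlineRoi logical ROI mask.
#' @param bgRois list of background-region masks (three regions just
#'   outside the germline, by convention).
#' @param wtReferenceMean mean wild-type ratio used as the normalizer
#'   (1 for the wild-type pass itself).
#' @param bgMode background mode, see [integratedDensityBgsub()].
#' @return list with `targetBgsub`, `controlBgsub`, `ratio`,
#'   `normalized`.
#' @export
fishLevel <- function(targetImg, controlImg, germlineRoi, bgRois,
                      wtReferenceMean = 1, bgMode = "region-mean") {
  t <- integratedDensityBgsub(targetImg, germlineRoi, bgRois,
                              bgMode = bgMode)
  c <- integratedDensityBgsub(controlImg, germlineRoi, bgRois,
                              bgMode = bgMode)
  if (c$corrected <= 0)
    stop("control channel nonpositive after background subtraction ",
         "(corrected = ", signif(c$corrected, 4),
         "); check background regions")
  ratio <- t$corrected / c$corrected
  list(targetBgsub = t$corrected, controlBgsub = c$corrected,
       ratio = ratio, normalized = ratio / wtReferenceMean)
}

#' Fraction of protein signal in condensate foci
#'
#' Intensity sum over all foci divided by the autofluorescence-corrected
#' total intensity sum of the oocyte region. Out-of-range fractions are
#' reported with a warning flag, never clamped, to surface calibration
#' problems (e.g. over-subtraction).
#'
#' @param stack 3-D intensity array.
#' @param oocyteRoi logical 3-D oocyte mask.
#' @param fociLabels integer 3-D label array (0 = background); foci must
#'   lie inside the ROI.
#' @param autofluorPerVolume autofluorescence per cubic micron estimated
#'   from untagged animals.
#' @param voxelVolume voxel volume (cubic micron).
#' @return list with `fociSum`, `totalSum` (corrected), `autofluorTotal`,
#'   `fraction`, and `flag` (`"ok"` or `"out-of-range"`).
#' @export
condensateFraction <- function(stack, oocyteRoi, fociLabels,
                               autofluorPerVolume = 0, voxelVolume) {
  stack <- as.array(stack)
  roi <- array(as.logical(oocyteRoi), dim(stack))
  foci <- array(as.integer(fociLabels), dim(stack))
  if (any(foci > 0L & !roi))
    stop("foci labels must lie inside the oocyte ROI")
  roiVolume <- sum(roi) * voxelVolume
  autofluorTotal <- autofluorPerVolume * roiVolume
  denom <- sum(stack[roi]) - autofluorTotal
  if (denom <= 0)
    stop("corrected total intensity is nonpositive; ",
         "autofluorescence correction exceeds the measured sum")
  fociSum <- sum(stack[foci > 0L])
  frac <- fociSum / denom
  flag <- if (frac < 0 || frac > 1) "out-of-range" else "ok"
  if (flag == "out-of-range")
    warning("condensate fraction ", signif(frac, 4),
            " outside [0, 1]; reported unclamped")
  list(fociSum = fociSum, totalSum = denom,
       autofluorTotal = autofluorTotal, fraction = frac, flag = flag)
}

#' Group comparison with the field's reporting conventions
#'
#' Two groups: Welch's unpaired t-test. Three or more: one-way ANOVA.
#' Per-group means come with t-based 95% confidence intervals.
#'
#' @param values numeric measurements.
#' @param groups group label per value.
#' @param conf.level confidence level for the per-group intervals.
#' @return list with `summary` (data.frame: group, n, mean, ciLow,
#'   ciHigh), `test` (`"welch-t"` or `"anova"`), and `p.value`.
#' @export
compareGroups <- function(values, groups, conf.level = 0.95) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  ns <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(ns < 2L)) stop("every group needs at least two values")
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    m <- mean(v); s <- stats::sd(v); n <- length(v)
    half <- stats::qt(1 - (1 - conf.level) / 2, n - 1L) * s / sqrt(n)
    data.frame(group = g, n = n, mean = m,
               ciLow = m - half, ciHigh = m + half)
  }))
  if (nlevels(groups) == 2L) {
    tt <- stats::t.test(values ~ groups)
    list(summary = summ, test = "welch-t", p.value = tt$p.value)
  } else {
    fit <- stats::aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    list(summary = summ, test = "anova", p.value = p)
  }
}
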