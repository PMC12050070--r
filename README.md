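# poreQuant

Quantification of nuclear-pore clustering and germ-granule colocalization
in fluorescence microscopy of the *C. elegans* germline.

In pachytene germ cells, nuclear pores are not spread uniformly over the
nuclear envelope: they gather into clusters of roughly 0.5–2 µm² that are
overlaid by P granules, the perinuclear germ-granule condensates that house
Argonaute proteins and RNA. Asking how strong that clustering is, and how
completely granules cover the clusters, turns into a handful of concrete
image measurements. poreQuant implements those measurements as a tested,
seed-deterministic pipeline, together with a synthetic-microscopy generator
that produces ground-truth-annotated images so every stage can be validated
without access to microscope data.

## What it measures

* **Clustering index** — the standard deviation of gray values over a
  cropped, max-projected nucleus. For a fixed number of pores and photon
  budget, clustering concentrates signal into fewer, brighter pixels, so the
  SD rises. Indices are normalized so the control-condition mean equals 1.0
  (`clusteringIndex()`, `normalizeToControl()`).
* **Cluster areas** — smooth once (3×3 mean), threshold with Otsu's method
  on a 256-bin histogram, label 8-connected components, report per-cluster
  areas in µm² with border-touching clusters excluded; histograms of total
  area binned by cluster area (`segmentClusters()`,
  `clusterAreaHistogram()`).
* **Pore/granule overlap** — the granule mask applied as a selection on the
  thresholded pore image gives the covered area fraction
  (`binarizeChannel()`, `overlapFraction()`); the fraction of clusters above
  an area cutoff (1.5 µm² for the headline statistic) overlaid by a granule
  (`largeClusterCoverage()`).
* **Granule geometry and partitioning** — intensity-weighted center-of-mass
  distances between granules (`comDistance()`), focus counts in a single
  plane (`countFociPlane()`), fraction of granule area in the rachis
  (`rachisGranuleFraction()`).
* **Intensity quantification** — background-subtracted integrated densities
  (`integratedDensityBgsub()`), germline/hypodermal nucleus ratios
  (`nucleusPanelRatios()`), FISH transcript levels normalized to a control
  transcript (`fishLevel()`), and condensate partition fractions with
  autofluorescence correction (`condensateFraction()`).
* **EM pore spacing** — center-to-center distances between adjacent pores
  along digitized electron-microscopy cross-sections
  (`adjacentDistances()`, `spacingHistogram()`).
* **Reporting** — Welch t-test / one-way ANOVA with 95% confidence
  intervals (`compareGroups()`), and a config-driven runner
  (`runPipeline()`) that emits one tidy CSV stamped with the configuration
  hash.

The generator (`simulateScene()` and friends) places pores on a spherical
envelope by a Matérn-style parent/offspring process with a von Mises–Fisher
angular kernel — one interpretable clustering knob, the offspring
concentration κ — overlays granule caps on a chosen fraction of clusters,
and renders two-channel voxel stacks through an anisotropic Gaussian PSF
with Poisson and read noise (both optional). Every random draw is governed
by an explicit seed and every scene carries a complete truth record.

## Worked example

```r
library(poreQuant)

## a clustered nucleus and an unclustered one, same pores and photons
wt  <- simulateScene(ClusterProcessParams(offspringConcentration = 20), seed = 1)
mut <- simulateScene(ClusterProcessParams(offspringConcentration = 0),  seed = 2)

clusteringIndex(cropSceneNucleus(wt))   # 15.24
clusteringIndex(cropSceneNucleus(mut))  # 11.86

## cluster areas on the clustered nucleus
cs <- segmentClusters(cropSceneNucleus(wt))
round(sort(clusterAreas(cs), decreasing = TRUE), 2)
#>    8    2    3    4    1   10   14    5   12    7   13    9    6   11
#> 1.75 1.61 1.33 0.94 0.59 0.13 0.07 0.05 0.05 0.04 0.04 0.03 0.02 0.02

## are large clusters covered by granules?
measureSceneCoverage(wt, areaThreshold = 0.3)$fraction  # 1
```

The clustered nucleus shows a ~29% higher gray-value SD than the uniform
one at identical pore count and photon budget — that contrast, normalized
to a control group, is the clustering index. Its five main clusters span
0.59–1.75 µm² (plus small fragments), and with full granule coverage
generated, every qualifying cluster is measured as covered.

A config-driven run over several conditions:

```r
cfg <- runConfig(nNuclei = 5, seed = 1,
                 conditions = c(control = 20, mutant = 0))
tab <- runPipeline(cfg, outputDir = "out")   # tidy CSV + histograms + config
```

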