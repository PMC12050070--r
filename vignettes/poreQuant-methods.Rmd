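---
title: "poreQuant: models, measurements, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poreQuant: models, measurements, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreQuant)
```

## The scientific problem

In the *C. elegans* pachytene germline, nuclear pores cluster on the
nuclear envelope and P granules — perinuclear germ-granule condensates —
sit on top of the large clusters. Quantifying this organization from
multi-channel confocal stacks requires a small set of standardized image
measurements: how clustered the pores are, how big the clusters are, what
fraction of pore area or of large clusters is covered by granules, how
transcripts and proteins partition between compartments, and how pores
space along the envelope in electron micrographs. poreQuant implements
each of these as an auditable function, and ships a synthetic-microscopy
generator so that each one is validated against known ground truth.

## The synthetic scene model

A nucleus is an idealized sphere (`EnvelopeModel`; default radius 2.5 µm,
shell thickness 0.1 µm). Pore centers are placed on the shell by a
Matérn-style cluster process: parent directions uniform on the sphere,
offspring directions von Mises–Fisher (vMF) around a uniformly chosen
parent. The single clustering knob is the vMF concentration κ
(`offspringConcentration`): κ = 0 is exactly uniform sampling, κ ≈ 20
gives clusters whose projected areas fall in the 0.5–2 µm² range reported
for pachytene nuclei. A configurable fraction of pores (default 25%) is
placed uniformly regardless of parents, reflecting the individual,
non-clustered pores seen between clusters. Defaults — 200 pores per
nucleus (≈2.5 pores/µm²), 8 parents — are configurable, deliberately so:
pachytene pore density and nucleus diameter are not pinned down by
published numbers, only the qualitative statement that germline density
exceeds somatic density.

Granules are solid spherical-cap shells abutting the envelope (default
angular radius 0.35 rad, thickness 0.4 µm), each centered over a cluster
after an angular jitter (half-normal, default SD 0.05 rad) that reproduces
the imperfect registration between clusters and overlying granules. A
coverage fraction *f* selects which clusters receive caps; `round(f·m)`
distinct clusters are capped.

Image formation renders each pore as an anisotropic Gaussian PSF
(σ~xy~ = 0.12 µm, σ~z~ = 0.35 µm) integrated *exactly* over voxels via the
normal CDF, so a punctum away from the border deposits its full photon
budget (default 500 photons) — noise-free stacks conserve photons to well
under 1%, which the tests assert. Caps are normalized to a per-cap budget
and blurred with the same PSF. Default voxels are 0.1 µm laterally and
0.5 µm axially over an 8 µm stack, matching high-resolution germline
acquisition settings. Noise is Poisson on signal-plus-background (default
background 10 photons) plus additive Gaussian read noise (SD 2), each
independently switchable so oracle tests can run noise-free.

Coordinates follow the pixel-center convention: the physical position of
0-based voxel index *i* is (*i* + 0.5) × voxel size; arrays are indexed
(y, x, z, channel).

The generator also emulates the pipeline's other inputs: 1-D Poisson (or
parent/offspring clustered) pore profiles for EM spacing, two-channel FISH
fields in which a central germline region carries target and control
signal over a shared background, and oocyte stacks whose photon budget is
split between Gaussian foci and a diffuse pool confined to the non-focus
oocyte volume — the condensate and dilute phases are disjoint, so the
generated partition fraction is exactly the measurable one.

### What the generator does not emulate

No FG-repeat cohesion physics, no diffusion or condensate dynamics, no
chromatin or nucleolar exclusion, no optical aberrations beyond the
Gaussian PSF, and no attempt to match absolute photon statistics of a
specific camera. Passing tests therefore demonstrate that the
*measurement* code recovers known truth under a faithful-but-idealized
image model; they do not certify performance on real data with debris,
neighboring nuclei, or spatially varying background.

## The measurement protocols

**Clustering index.** Stacks are max-projected (10 µm depth by
convention, centered on the midplane; shallower stacks use all planes —
the projection depth is recorded in provenance), individual nuclei are
cropped, and the index is the standard deviation of gray values in the
crop. We use the population (divide-by-*n*) SD: the reported quantity is
always a ratio to a control-group mean, for which the n vs n−1 choice is
immaterial at realistic crop sizes, but the choice is documented and
switchable (`type = "sample"`). `normalizeToControl()` divides by the
control mean so the control averages exactly 1.0. The index is exactly
invariant under gain changes after normalization, and under integer-pixel
translation of the crop.

**Cluster segmentation.** "Smoothed once" is one pass of a 3×3 uniform
mean filter with edge pixels averaging their in-bounds neighbors, the
behavior of the standard interactive smoothing command. Otsu's threshold
is computed on a 256-bin histogram spanning the smoothed image's own
intensity range, maximizing between-class variance with the first maximum
taken on ties; foreground is strictly above the threshold. Components are
labeled with 8-connectivity. Components touching the crop border are
excluded from the area list (and recorded), mimicking the manual practice
of avoiding clusters on the edge of nuclei. Areas are pixel counts times
pixel area. Histograms report both the total area per bin (the protocol's
headline output) and the cluster count per bin, since figure legends in
this field sometimes show frequency rather than summed area; bins are
half-open `[lo, hi)` and the edges are a configuration item.

**Overlap and coverage.** Channels are thresholded (Otsu by default, fixed
value as an override — the overlap protocol's threshold method is not
standardized, so it is a recorded parameter), the granule mask is applied
as a selection on the pore mask, and the covered fraction is intersection
area over pore-mask area. A cluster counts as "overlaid" if its label
intersects the granule mask in at least `minOverlapPx` pixels (default 1,
i.e. any overlap — the binary scoring used for the large-cluster
statistic). When no cluster exceeds the area cutoff the result is `NA`
with counts, never a silent zero. For synthetic-scene validation,
`measureSceneCoverage()` thresholds the granule channel at a fixed level
above the known background (background + 5√background + 3×read-noise SD)
rather than by Otsu, because a scene generated with zero coverage has a
granule channel of pure background on which Otsu is undefined
(degenerate histogram) — a measurement-harness choice, recorded in the
mask provenance.

**Focus counting.** Manual counting is replaced by a documented detector:
Gaussian smoothing at the spot scale (default σ = 1.5 px), strict local
maxima over the 8-neighborhood, and a prominence test against the plane
median (default 10 intensity units). Two spots inside the smoothing scale
merge into one detection; this is asserted, not hidden. The same detector
logic underlies the foci used in condensate-fraction scenes.

**Intensity quantification.** Integrated densities are background
subtracted as `sum(ROI) − bg × |ROI|` where `bg` is, by default, the
average of the per-region mean intensities of the background ROIs
("average fluorescence of three regions"); pooled-pixel averaging is an
option, and the two agree for equal-size regions. All corrected
quantities are exactly invariant to a constant offset applied to the
whole image. FISH levels form the target/control corrected ratio and then
normalize by a wild-type reference mean so the wild-type group averages
1.0; a nonpositive corrected control is an error with diagnostics, not a
silent negative. Condensate fractions divide the foci intensity sum by
the autofluorescence-corrected oocyte total; out-of-range fractions are
flagged and reported unclamped, surfacing calibration problems instead of
masking them.

**EM spacing.** Adjacent-pore distances are consecutive center-to-center
gaps along the digitized contour, each adjacency counted once (n−1 gaps
for n pores). The per-pore reading — both neighbors of every interior
pore — only duplicates every gap and rescales the histogram, so it is
provided as a documented toggle rather than a default. The pore-diameter
convention (default 110 nm, the middle of the 100–120 nm fusion-site
band) is carried on the profile for interpretability. Homogeneous
profiles have exponential gaps; the tests verify the closed form by
Kolmogorov–Smirnov distance at n ≈ 2000.

**Group statistics.** Two groups are compared with Welch's unpaired
t-test, three or more with one-way ANOVA; group means carry t-based 95%
confidence intervals. This is reporting plumbing around `stats`, not new
methodology.

## Numerical choices and degenerate inputs

Otsu is undefined on constant images: segmentation and Otsu binarization
raise a degenerate-input error rather than guessing. Empty reference
masks, empty ROIs or background regions, profiles with fewer than two
pores, and nonpositive normalizers are all errors with specific messages.
Ties in the Otsu objective take the first maximum. Bins everywhere are
half-open `[lo, hi)`. The connected-component labeler propagates labels
to a fixed point, which is exact; tests verify it against a BFS flood
fill. Rendering refuses geometry closer than 4σ to the stack border so
the photon-conservation contract is meaningful.

## Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state; the same seed gives bit-identical output, which the tests
assert. `runPipeline()` executes a declarative JSON-serializable
configuration and stamps every output row with the configuration's MD5
hash; rerunning a logged configuration reproduces the output files
byte-for-byte. Stacks are written as 16-bit multi-page TIFF with an
integer quantum recorded in a JSON sidecar alongside voxel sizes, channel
names and the full generator truth, so integer-valued (photon-count)
stacks round-trip exactly; reading a TIFF with no sidecar requires an
explicit voxel-size override.

## Validation scale and known limitations

The validation suite runs at desk scale: 20 nuclei per condition for the
clustering-index and coverage sweeps, 10 fields per FISH ratio, ~2000
pores per EM profile — sizes chosen so the full suite completes in a few
minutes while leaving Monte-Carlo error well inside the asserted
tolerances.

Two limitations are worth stating plainly. First, projections of a full
spherical shell superpose the front and back surfaces and brighten the
rim where the shell is viewed tangentially; segmentation on whole-nucleus
projections therefore reflects cluster topology less cleanly than on the
face-on test scenes, and coverage estimates at intermediate generated
fractions are biased upward (they remain exact at 0 and 1 and monotone in
between — which is what the validation asserts). Second, the SD
clustering index is insensitive to *weak* clustering: at κ = 2 the index
rises only ~2% over uniform while nucleus-to-nucleus variability is ~3%,
so with 20 nuclei per group the 95% confidence intervals of adjacent weak
conditions can touch even though the means order correctly. Strong
contrasts (κ = 20 vs uniform, a ~30–40% index change) separate
decisively. Users comparing subtle conditions should plan larger group
sizes than 20 nuclei.
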