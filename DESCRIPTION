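Package: poreQuant
Title: Quantification of Nuclear-Pore Clustering and Germ-Granule Colocalization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for nuclear-pore clustering and
    P-granule/nuclear-pore colocalization in the C. elegans germline.
    Provides a synthetic-microscopy generator (clustered point processes on
    spherical nuclear envelopes, Gaussian-PSF image formation, Poisson and
    read noise) with full ground-truth records, and the measurement stages
    that consume such images: the gray-value standard-deviation clustering
    index with control normalization, mean-filter + Otsu cluster-area
    segmentation and binned area histograms, mask-overlap colocalization and
    large-cluster coverage, intensity-weighted center-of-mass distances,
    focus counting, rachis granule partitioning, background-subtracted
    integrated densities, FISH levels with control-transcript normalization,
    condensate partition fractions, and adjacent-pore spacing statistics
    from EM cross-sections. Includes group-comparison reporting (Welch
    t-test, one-way ANOVA, 95% confidence intervals) and a config-driven,
    seed-deterministic pipeline runner with tidy CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'colocalization.R'
    'em-spacing.R'
    'intensity-quant.R'
    'io.R'
    'methods-accessors.R'
    'pipeline.R'
    'pore-clustering.R'
    'poreQuant-package.R'
    'synthetic.R'
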