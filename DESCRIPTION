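Package: pulldownQuant
Title: Quantification of Microscopy-Based Bead Pull-Down and Condensate Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying on-bead protein-protein interaction assays
    and condensate formation assays read out by fluorescence microscopy, as
    used to study recognition of aggregated cargo by autophagy receptors.
    Detects beads in a fluorescence channel, fits circular regions of
    interest, draws radial line profiles and scores each by its min-max gray
    value difference, excludes profiles protruding into adjacent beads, and
    applies a per-bead dispersion filter. Counts condensates over time after
    rolling-ball background correction and computes cross-channel
    colocalization fractions. Normalizes fluorescence recovery after
    photobleaching (FRAP) traces and estimates mobile fractions. Provides the
    matching inference layer (Student t tests, two-way ANOVA, and linear
    mixed models with replicate and well as random factors) and targeted
    mass-spectrometry normalization rules for ubiquitylation-site intensities
    (reference-peptide and gel-section normalization with paired log2
    ratios). A synthetic-data module generates bead scenes, condensate
    series, FRAP traces, nested bead tables and paired peptide tables with
    machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    lme4,
    lmerTest,
    car,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Proteomics, Visualization
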