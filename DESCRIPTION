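Package: stressvbm
Title: Receptor-Expression-Weighted Voxel-Based Morphometry of the Cortisol
    Awakening Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating the cortisol awakening response (CAR) to
    grey-matter volume under a diathesis-stress design. Implements quality
    control and Pruessner area-under-the-curve summaries for three-point
    waking salivary cortisol series, pooled two-sample group statistics with
    standard-score outlier screening, aggregation of sample-level
    glucocorticoid and mineralocorticoid receptor expression to atlas
    regions, a rank-based flexible multiple-comparison thresholding scheme
    spanning P<0.01 uncorrected to P<0.05 Bonferroni-corrected within the
    mask, voxelwise general linear models for the CAR correlation and its
    group interaction, and a synthetic-data module that generates every
    input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
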