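Package: ToftsPK
Title: Tofts Pharmacokinetic Modelling and Treatment-Response Statistics
    for DCE-MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pharmacokinetic analysis of dynamic contrast-enhanced MRI of
    head-and-neck tumours: dual-flip-angle spoiled-gradient-echo T1 mapping,
    signal-to-gadolinium-concentration conversion, arterial input function
    extraction with hematocrit correction, voxel-wise Tofts model fitting
    (Ktrans, kep, ve) with goodness-of-fit filtering, area under the
    gadolinium concentration-time curve (AUGC), region-of-interest summaries
    with pre/post-treatment percent change, and an outcome-statistics layer
    (logistic regression with odds ratios, stepwise selection, paired t-tests,
    ROC analysis with Youden-index thresholds, diagnostic-performance tables
    and Fisher's exact test). A synthetic phantom and cohort generator with
    known ground-truth kinetics supports end-to-end validation without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
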