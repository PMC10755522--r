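Package: bagpipe
Title: Brain Age Gap Estimation from Regional Neuroimaging Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nested cross-validated brain age estimation from regional
    neuroimaging features (gray-matter volume from MRI or SUVR from FDG-PET),
    with age-bias correction, ensemble inference on clinical cohorts, and
    downstream statistics: permutation feature importance over atlas regions,
    covariate-adjusted partial correlations of the brain age gap with
    cognition and pathology markers, ANCOVA group comparisons, and
    residualized single-feature logistic prediction of progression from mild
    cognitive impairment to dementia.  Includes a synthetic cohort generator
    with known ground truth so the whole pipeline is testable without access
    to restricted clinical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    e1071,
    kernlab,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
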