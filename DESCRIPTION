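Package: tiquant
Title: Quantitative Immunohistochemistry, Flow Gating and Cytokine
    Calibration for Preclinical Tumor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration-based quantitative immunohistochemistry
    (microvessel density, alpha-SMA coverage, vessel maturation index,
    macrophage area fraction, Ki67 positivity, necrosis fraction),
    sequential flow-cytometry gating of myeloid populations with
    CD38/CD206 macrophage quadrant phenotyping, four-parameter logistic
    standard-curve quantification of multiplex bead assays, and the
    accompanying statistical layer (exact rank-sum comparisons,
    Pearson correlation, median-absolute-deviation outlier screening
    and sample-exclusion rules).  Includes a synthetic-data generator
    that plants machine-readable ground truth in every input so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
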