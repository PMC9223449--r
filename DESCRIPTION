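Package: mocamet
Title: Two-Block Metabolomics of Aneurysmal Risk via Joint-Unique
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for targeted two-block (plasma and aorta)
    metabolomics of experimental aortic aneurysm. Implements a multiblock
    orthogonal component analysis (an O2PLS/OnPLS-style decomposition)
    separating variance shared between tissue blocks from block-unique
    variance, Kendall tau-b variable importance on the first joint
    component with Benjamini-Hochberg false-discovery-rate control,
    biochemical class sums and ratio biomarkers (BCAA/Gly, LysoPC/PC,
    unsaturated-to-saturated LysoPC), and single-feature classifier
    evaluation by ROC AUC with DeLong confidence intervals. Ships a
    synthetic cohort generator emulating a three-group mouse design on a
    p180-style metabolite panel, providing ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
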