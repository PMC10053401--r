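Package: acbtools
Title: Antioxidant-Capacity Biomarker Discovery for Redox-Targeting Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and applying multi-gene expression
    biomarkers of sensitivity to ROS-inducing (redox-targeting) drugs in
    cancer cell line panels. Implements gene-wise Pearson association of
    expression and proteomics layers with drug sensitivity, rank-combined
    signature selection, signature scoring and greedy signature reduction,
    compound-similarity search in signature-correlation space with ROC
    enrichment of chemically reactive compounds, four-parameter logistic
    dose-response fitting, the normalized growth-rate (GR) metric, and
    redox-probe oxidation (OxD) normalization. A synthetic-data module
    generates expression panels with a planted co-regulated signature
    block, matched noisy proteomics, compound libraries, dose-response
    curves and growth counts with known ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
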