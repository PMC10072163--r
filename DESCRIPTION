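Package: metpoly
Title: MET Copy-Number Status Calling from Targeted NGS Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes focal MET amplification from chromosome 7
    polysomy in targeted next-generation sequencing copy-number profiles.
    Off-target bins on chromosome 7q are aggregated per cytoband, adjacent
    bands are compared by t-tests, non-significantly different bands are
    grouped into regions and iteratively merged, and the fraction of the
    arm carrying a copy-number gain together with the MET gene copy number
    yields a four-way status call (negative, MET amplification, pan-MET
    amplification, polysomy). Also provides the ROC/Youden-index procedure
    used to set the polysomy copy-number cutoff, diagnostic-agreement
    statistics (confusion matrices, one-vs-rest metrics, Cohen's kappa,
    MSAF-stratified tissue-plasma percent agreement), and a seeded
    synthetic profile generator for tissue and plasma with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
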