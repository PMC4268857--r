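Package: stromalens
Title: Stroma-Aware Integration of Histology Images and Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the stromal fraction of H&E-stained tumour sections by
    entropy-based tissue masking, Ruifrok colour deconvolution and Otsu
    thresholding, links the image-derived fractions to gene expression through
    stromal signature scoring and correlation ranking, and carries the
    correction through to downstream analyses: quartile-contrast differential
    expression with a moderated t-statistic, running-sum gene-set enrichment,
    compartment-specific differential expression on known cell fractions, and
    left-truncated Cox survival models for dichotomised tumour markers. Ships
    a synthetic-data generator producing histology tiles, two-compartment
    expression mixtures with copy-number structure, staining categories and
    delayed-entry survival cohorts with known ground truth, so that the whole
    pipeline can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
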