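Package: pictscreen
Title: Colocalization Scoring, Hit Calling and FRAP Analysis for PICT
    Imaging Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative readout for protein interactions from imaging of
    complexes after translocation (PICT) assays in budding yeast. Two-channel
    fields (anchor-RFP, prey-GFP) are background-corrected by rolling-ball
    subtraction, segmented by local-mean thresholding into punctate masks, and
    scored by the area of mask intersection normalized to the anchor-mask
    area. Per-strain recruitment is tested with a one-tailed heteroscedastic
    (Welch) t-test across fields of view acquired with and without rapamycin,
    and hits are called from the p-value and the +RAP/-RAP colocalization
    ratio. A synthetic-microscopy generator (cells with cortical anchor
    puncta, cytosolic or punctate prey, Gaussian optics, Poisson shot noise,
    camera read noise) provides ground-truth screens, and a FRAP module
    simulates, normalizes, aggregates and fits bleach-recovery curves to
    quantify prey exchange at anchor sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
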