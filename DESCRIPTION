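Package: tfhic
Title: Transcription Factor Enrichment in High-Intensity Hi-C Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transcription factors whose binding sites are enriched
    in high-intensity (mainly inter-chromosomal) chromatin interactions in
    yeast. Implements fixed-width 1-kb genome binning of Hi-C contact lists,
    read-count and genomic-separation filters, per-factor overlapping-ratio
    curves across read-count thresholds, a chi-square threshold scan with
    Bonferroni control, a bootstrapped elastic-net selection of factors whose
    overlapping ratio tracks interaction intensity, a trend-in-proportions
    comparison, and the intersection of the two methods. Ships a synthetic
    contact/binding-site generator with planted factor effects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
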