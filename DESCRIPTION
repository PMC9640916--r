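Package: cernet
Title: Competing Endogenous RNA Network Inference for the Hair Follicle Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for inferring lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) networks across the murine hair follicle cycle
    (anagen, catagen, telogen). Provides phase-wise dual fold-change screening
    of miRNAs, two-group differential expression with fold-change and t-test
    thresholds, multi-source miRNA target-prediction intersection with
    experimental-evidence and subcellular-localization filtering,
    sponge-degree screening of candidate lncRNAs, exhaustive triplet network
    assembly with SIF export, hypergeometric over-representation analysis
    with Benjamini-Hochberg correction, relative quantification of qPCR data
    by the 2^-ddCt method, and a synthetic-data generator with a ground-truth
    manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
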