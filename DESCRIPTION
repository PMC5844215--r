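Package: snpminer
Title: Mining SNP-Disease Associations from PubMed Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts single-nucleotide polymorphism (SNP) to disease
    association records from biomedical abstracts: dbSNP rsID mentions,
    P-values and odds ratios in their common notational dialects,
    patient/control cohort sizes via numeric-modifier matching, and cohort
    ethnicity via nationality entity recognition. Couples statistics to
    SNP mentions with a nearest-unconsumed heuristic (with single-value
    broadcast), assembles sortable tabular reports, scores extractions
    against gold annotations with precision/recall/F1, and generates
    gold-labelled synthetic abstracts so the whole pipeline is testable
    offline. Supports live PubMed retrieval through NCBI E-utilities as
    well as offline PubMed XML and plain-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
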