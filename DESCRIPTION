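Package: guidescreenr
Title: Genome-Wide sgRNA Design and Off-Target Screening for Bacterial CRISPRi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design single-guide RNAs (sgRNAs) for chromosomally encoded,
    arabinose-tunable CRISPR interference in bacteria. Validates annotated
    open reading frames (NTG starts, TAG/TGA/TAA stops), enumerates
    CC-prefixed PAM-anchored candidate sites near each start codon, screens
    specificity genome-wide with canonical k-mer abundance tiers (10/15/23-mer,
    CT/TC near-PAM variants, 1-4 mismatch Hamming tiers), emits 90-nt
    single-step recombineering oligos (35 + 20 + 35 nt), audits off-target
    effects in paired expression tables via match-tier gene subsets, and fits
    sigmoid dose-response and gamma fluorescence-distribution models. Includes
    seeded synthetic-fixture generators so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    S4Vectors,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    fitdistrplus,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
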