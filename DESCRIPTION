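Package: dawnreg
Title: Photoperiod- and PIF-Dependent Gene Expression Analysis at Dawn
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for defining photoperiod-regulated
    genes at dawn from normalized log2 expression matrices of wild-type and
    pifq (quadruple phytochrome-interacting-factor mutant) Arabidopsis
    seedlings grown under short days (SD) or free-running light (LL).
    Implements per-gene two-group contrasts with fold-change plus FDR gating
    (SS1.5F), sign-concordant intersection classification into PIF/SD-induced,
    PIF/SD-repressed and ambiguous sets, a percent-contribution statistic
    quantifying how much of the wild-type night response is attributable to
    the PIF quartet, strand-aware IUPAC promoter-motif scanning with
    hypergeometric enrichment (G-box, PBE, extended G-box/PBE, ABRE), and
    cosine-template diurnal phase assignment with rhythmicity calling and
    phase-bin enrichment. A synthetic-data generator with planted ground
    truth makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
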