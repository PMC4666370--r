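Package: srnatarget
Title: Ensemble-Based Small RNA Target-Site Prediction and Ribo-Seq Target Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial small RNA (sRNA) binding sites on target mRNAs
    with an ensemble-based thermodynamic model: Boltzmann sampling of RNA
    secondary structures (McCaskill partition function with stochastic
    traceback), identification of high-accessibility hairpin-loop seed regions
    on the sRNA, intermolecular duplex prediction by dynamic programming, and a
    total free-energy criterion that balances hybrid stability against the cost
    of disrupting intramolecular structure on both molecules
    (dG_total = dG_initiation + dG_hybrid - (dG_T-disruption + dG_S-disruption);
    a site is called when dG_total < 0). Also provides target calling from
    paired RNA-seq/Ribo-seq differential-expression tables (coverage floor,
    fold-change threshold, direction) with classification of the regulatory
    mode (translational versus mRNA stability), compensatory-mutation pairing
    analysis, and seeded synthetic-data generators so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
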