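Package: mutselpip
Title: Detecting Clade-Specific Shifts in Amino Acid Preference with
    Mutation-Selection Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon-level mutation-selection substitution models with a finite
    mixture of amino acid fitness profiles, MCMC sampling of site-to-profile
    allocations (count-based Gibbs and weight-demarginalised variants), and
    the probability-of-identical-profiles (PIP) statistic for detecting
    site-specific shifts in amino acid preference between a designated
    monophyletic sub-clade and the remainder of a phylogeny.  Includes a
    simulator for codon alignments with embedded sub-clade profile shifts,
    biochemically grouped profile constructors with controllable peakedness,
    readers for empirical finite-mixture profile tables, and evaluation
    utilities (TPR/FPR, precision-recall).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
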