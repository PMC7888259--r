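Package: peptidomics
Title: Endogenous Peptidome Profiling from Spectral-Count Peptide Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of endogenous peptidomes (e.g. wound fluids) from
    label-free peptide identification tables with spectral counts. Provides
    readers for delimited peptide tables and FASTA databases, replicate
    concatenation and spectral-count filtering, peptide-to-protein
    localization with P1/P1' cleavage-site derivation, spectral-count
    weighted amino-acid composition and MEROPS-style terminal tetrapeptide
    profiling, set algebra between samples and groups (Venn regions,
    intersectional and differential peptides), protein substrate abundance,
    rule-based protease attribution, antimicrobial scoring with per-protein
    coverage profiles and region-confined spectral sums, literature
    cross-matching, and an in-silico proteolysis simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
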