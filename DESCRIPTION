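Package: gpcrsel
Title: Evolutionary and Structural Determinants of G Protein-Coupling
    Selectivity in Aminergic GPCRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies receptor-wide amino-acid positions associated with
    G protein-coupling selectivity in aminergic G protein-coupled
    receptors. Provides ortholog-restricted conservation scoring with
    BLOSUM80 substitution tolerance, gene-tree ortholog extraction and
    diverged-paralog trimming, coupler versus non-coupler specificity
    enrichment, residue-residue contact score (RRCS) networks between
    activation states, group-wise contact-change statistics, and
    molecular-dynamics trajectory contact analysis with GPCRdb
    activation-state classification. Includes synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
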