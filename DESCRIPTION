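Package: emmtools
Title: Ensemble Molecular Mimicry Detection from Protein Thermodynamic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting ensemble molecular mimicry between proteins
    from sequence-derived thermodynamic profiles. Per-residue thermodynamic
    descriptors are encoded as an eight-letter thermodynamic-environment
    alphabet, aligned gaplessly against amino-acid sequences with an
    environment-by-amino-acid substitution matrix and extreme-value calibrated
    significance (eTFR), and compared locally by windowed 8xL cosine similarity
    (fragment vector comparison, FVC). A correlation pipeline links computed
    thermodynamic similarity to antibody-binding Z-scores from proteome
    microarrays, including the S x f local-similarity weighting and a
    BLOSUM62 local-alignment sequence-identity control. Synthetic fixture
    generators reproduce the statistical structure of the study design for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
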