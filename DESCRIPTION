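Package: disprof
Title: Sequence-Based Profiling of Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles intrinsically disordered proteins (IDPs) from the
    amino-acid sequence alone. Computes Henderson-Hasselbalch fractional
    charges and net charge under selectable pKa sets (IPC_protein by
    default), scaled Kyte-Doolittle hydropathy, sliding-window local
    charge and hydropathy profiles, charge-hydropathy (Uversky)
    classification of whole sequences, FoldIndex windowed disorder
    prediction with region segmentation, structural-tendency residue
    classification and compositional summaries, per-residue sequence-map
    layouts, and reading/validation of amino-acid substitution matrices
    (including IDP-derived families supplied as files). Results are tidy
    tibbles with ggplot2 visualisations and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
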