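Package: structptm
Title: Structural Context of Posttranslational Modifications from
    Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse posttranslational modification (PTM) sites in the
    context of AlphaFold-style predicted protein structures. Implements
    the prediction-aware part-sphere exposure (pPSE) metric, which counts
    alpha-carbon neighbours inside a cone around the side-chain direction
    with distances inflated by the predicted aligned error (PAE); calls
    intrinsically disordered regions (IDRs) and short IDRs from smoothed
    full-sphere exposure; joins PTM site tables to structural
    annotations; computes exposure-aware sequence-motif statistics and
    log-odds position-specific scoring matrices; and tests 3D
    co-modification with PAE-aware binned proximity profiles and
    per-protein permutation cluster tests. A synthetic-structure
    generator (helices, coils, globular segments, chimeras, simulated
    PTM placement) makes the whole pipeline testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
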