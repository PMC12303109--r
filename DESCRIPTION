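Package: rdgnscreen
Title: Candidate Screening for Retinal Determination Gene Network Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates two-cell-line RNA-seq expression profiles (Drosophila
    Kc167 and S2) with seed-centred protein-protein interaction subnetworks to
    nominate candidate members of the retinal determination gene network headed
    by the Pax6 paralogues eyeless and twin of eyeless. Implements TPM
    normalisation, pseudocounted log2 fold-change classification, seed
    subnetwork construction with within-subnetwork connectivity, the combined
    connectivity/expression candidate screen with network-specificity calls,
    and position-weight-matrix scanning of enhancer sequences with
    percentile-calibrated score thresholds and a composition-preserving
    scrambled-sequence enrichment null. A synthetic-data module generates
    expression tables, planted-cluster interaction graphs, PWM training sets
    and motif-planted enhancers so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
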