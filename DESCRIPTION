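Package: napscan
Title: Genome Occupancy and Ligand-Binding Analysis for a c-di-GMP-Regulated
    Nucleoid-Associated Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the genome occupancy and ligand binding of a
    c-di-GMP-responsive nucleoid-associated protein. Computes per-position
    log2(IP/input) ChIP enrichment and calls peaks at a fold-enrichment
    threshold with summits and ranks; models direct-repeat binding motifs as
    position weight matrices, scans both genome strands with log-odds scores,
    and calibrates empirical p-values against a Monte-Carlo null of GC-matched
    random sequences; associates motif hits with peak summits and classifies
    peaks as genic or intergenic; and fits study-style quantitative binding
    models (one-site isothermal titration calorimetry isotherm, EMSA
    fraction-bound dissociation constants, mutually exclusive ligand
    competition, per-cell copy-number conversion, immunoblot and
    size-exclusion standard curves, comparative-Ct expression ratios). A
    synthetic-data module generates GC-matched genomes, planted motif sites,
    gene annotations and paired IP/input coverage so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
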