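Package: koprofiler
Title: KEGG Ortholog Profiling and Differential Abundance for Shotgun
    Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional profiling of shotgun metagenomic and
    metatranscriptomic samples from protein-alignment tabular output
    (BLAST/DIAMOND outfmt 6). Resolves reads to best-hit KEGG Orthology
    (KO) groups, quantifies KO abundance as raw counts and
    protein-length RPKM, tests for differentially abundant KOs across
    sample groups (Kruskal-Wallis or quasi-Poisson), and performs
    operon- and pathway-level enrichment with Fisher's exact test.
    Includes KEGG pathway-map color export, heatmap matrices, a
    seed-reproducible synthetic-data generator with known ground truth,
    and a one-shot pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
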