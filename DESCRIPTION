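Package: magbinr
Title: Bubble-Chart Binning, Quality Metrics and Comparative Genomics for
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs bin genomes (metagenome-assembled genomes) from
    shotgun-metagenome contigs by manual bubble-chart selection in G+C x RPKM
    space, refines bins by tetranucleotide-frequency coherence and
    single-copy marker de-duplication, and scores bins by marker-based
    completeness, predicted genome size and relative read abundance.
    Also provides bidirectional best-hit (BBH) ortholog comparison of
    predicted proteomes with three-way Venn partitioning, neighbor-joining
    phylogenies with bootstrap support, and a seeded synthetic-community
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
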