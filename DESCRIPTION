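Package: taxvote
Title: Voting-Based Taxonomic Classification of Contigs and
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies long metagenomic contigs and metagenome-assembled
    genomes (MAGs) on the NCBI taxonomy by combining per-ORF last common
    ancestor (LCA) assignment with bit-score-weighted voting across all
    ORFs of a query. Protein-versus-database alignments (BLAST/DIAMOND
    tabular format) are the input; per ORF, hits within a configurable
    bit-score range of the top hit are collapsed to their LCA, and the
    top-hit bit-score is the ORF's vote weight. A query is assigned to
    the deepest taxon whose summed vote exceeds a configurable fraction
    of the total. Includes loaders for NCBI taxdump and protein
    accession-to-taxid mappings, clade-exclusion benchmarking, contig-set
    and base-pair (CAMI-style) scoring, and a seeded synthetic-data
    generator so the whole pipeline is testable offline at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
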