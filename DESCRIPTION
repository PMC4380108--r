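Package: genefish
Title: Targeted Iterative Assembly of Loci from Paired-End Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fishes individual genes out of a paired-end short-read library
    without assembling the whole genome. Reads are hashed into approximately
    equal shards with an index of first-end reads and a mate lookup store; a
    DNA or protein query is searched against each shard with a seed-and-extend
    local aligner (translated in all six frames for protein queries), top hits
    and their mates are pooled and assembled with a built-in de Bruijn graph
    assembler, and the resulting contigs become the queries of the next
    iteration until the locus is complete. Includes stopping rules (exact
    contig convergence and an autocomplete test against the query ends),
    validation metrics (percent coverage, uncorrected p-distance, reciprocal
    best-hit orthology), multi-sample/multi-target pipelines with
    reference-anchored alignments, and a simulator of intron-bearing genomes,
    diverged homologs and paired-end read libraries for fully self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
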