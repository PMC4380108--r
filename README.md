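# genefish

Targeted iterative assembly of individual loci from a single paired-end
short-read library — no whole-genome assembly, no close reference genome
required.

**Who it is for.** Phylogenomics and comparative genomics projects that need
hundreds to thousands of orthologous genes per sample from Illumina-style
paired-end data, including samples tens of millions of years diverged from
the nearest annotated reference. Instead of assembling each genome and
mining it, genefish assembles only the reads that belong to each locus of
interest.

## The method

Given a read library and a query sequence *q* (DNA or protein):

1. **Shard.** Read pairs are hashed by fragment id into approximately equal
   shards. Each shard indexes its first-end reads for search and stores both
   mates for retrieval. Because the hash ignores sequence content, every
   shard is a uniform random sample of the library; searching a fraction
   *f* of shards downsamples the effective coverage to *f·C*.
2. **Search** (iteration 0). *q* is compared with every indexed read by
   seed-and-extend local alignment — exact shared words (12 nt, or 4 aa
   against all six reading frames of each read for protein queries) extended
   by affine-gap local DP. The top hits *and their mates* are pooled.
3. **Assemble.** The pool is assembled with a de Bruijn graph assembler
   (canonical *k*-mers, *k* = 31, count filtering, unitig extraction).
4. **Iterate.** Contigs are scored against the *original* query; the best
   become the next iteration's search queries. Each round the mates of newly
   matched reads extend the assembly outward — across introns and into
   flanks the query never covered. The loop stops on contig-set
   convergence, on an *autocomplete* test (a contig's alignments reach both
   ends of *q*), at the iteration cap, or with `no_hits`.
5. **Validate.** Percent coverage of a reference, uncorrected p-distance
   (`p = differing / comparable sites`, gap and ambiguous columns
   excluded), and a reciprocal best-hit orthology test against the whole
   reference protein set. Grid pipelines run many targets across many
   samples and emit one reference-anchored alignment per locus.

A bundled simulator (genomes with intron-bearing genes, diverged homologs,
paired-end reads with substitution errors) makes the whole package testable
with no external data. See the methods vignette
(`vignettes/targeted-assembly.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(genefish)

# 1. simulate a 30 kb genome with three intron-bearing genes and a 30x
#    paired-end library (stand-ins for your FASTQ files)
genome <- simulate_genome(30000, n_genes = 3, seed = 42)
pairs  <- simulate_paired_reads(genome, coverage = 30, error_rate = 0, seed = 7)

# 2. build the sharded read database
db <- build_db(pairs, "reads_db")
db
#> <genefish_db> 4500 read pairs in 1 shard(s)
#>   path: reads_db
#>   salt: v1  fingerprint: 45deb43414158fa9

# 3. fish out gene01 using its spliced coding sequence as the query
target <- tibble::tibble(id = "gene01", seq = gene_cds(genome, "gene01"))
res <- run_genefish(db, target, genefish_params(autocomplete = TRUE))
res
#> <genefish_result> target 'gene01': autocomplete after 1 iteration(s)
#>   best contig: c1 (1042 bp, score 1105)
tidy(res)
#> # A tibble: 1 x 8
#>   iteration n_hits n_pairs_in_pool n_contigs n_kept best_score best_length status
#>           0    100             100         4      1       1105        1042 autocomplete

# 4. validate the best contig against the truth
contig_stats(
  tibble::tibble(contig_id = res$best_contig$contig_id,
                 seq = res$best_contig$seq, reference_id = "gene01"),
  target)
#> # A tibble: 1 x 6
#>   contig_id reference_id percent_coverage p_distance ...
#> 1 c1        gene01                      1          0
```

The 741 bp spliced query pulled in 100 read pairs, and one iteration
assembled a 1042 bp contig — the full gene *including its intron and
flanks* — that covers 100% of the query at p-distance 0. Real FASTQ files
enter the same way via `read_seqs()` + `pair_reads()` (or the command-line
front-end in `inst/cli/genefish.R`: `format_db`, `assemble`, `stats`, `sim`,
`assembly-pipeline`, `alignment-pipeline`).

For protein queries from a divergent reference, pass an amino-acid sequence
as the target; iteration 0 switches to translated search automatically.

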