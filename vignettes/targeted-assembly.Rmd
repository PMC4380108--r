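---
title: "Targeted iterative assembly: the method behind genefish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted iterative assembly: the method behind genefish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phylogenomic and comparative studies usually need a few hundred to a few
thousand orthologous loci per sample, not whole genomes. Assembling a draft
genome from one paired-end Illumina library only to harvest 1% of it wastes
compute and often fails outright when no close reference exists. genefish
assembles one locus at a time directly from the read library: it finds the
reads related to a query, assembles only those, and repeats with the growing
contigs until the locus is complete. Because the query may be a protein from
a distant relative, loci can be fished out of libraries tens of millions of
years diverged from the reference taxon.

## The procedure

1. **Database build** (`build_db()`). Read pairs are hashed by fragment id
   into `n_shards` approximately equal shards (salted FNV-1a with an
   avalanche finalizer, so placement is stable across platforms and
   sessions). Each shard stores its first-end reads for searching and both
   mates for retrieval. Because a hash of the read *name* is independent of
   sequence content, every shard is a uniform random sample of the library;
   searching a fraction of shards (`fraction`) downsamples coverage without
   bias.
2. **Search** (`search_shard()`). A seed-and-extend local aligner: exact
   shared words (12 nt for DNA, 4 aa for protein queries) nominate candidate
   reads, which are extended by exact affine-gap local dynamic programming
   on a query window spanning the seed diagonals. DNA queries are searched
   against both read orientations; protein queries against all six
   translated frames (stops rendered `*`, which mismatches everything).
   Hits are thresholded on raw alignment score, sorted (ties broken by
   fragment id, making truncation reproducible), and the top
   `top_n_per_shard` kept per query.
3. **Pool and assemble** (`gather_read_pool()`, `assemble_reads()`). Top
   hits and their mates are pooled across shards, deduplicated, and
   assembled with a built-in de Bruijn graph assembler: canonical k-mers
   (k = 31) counted over both strands, k-mers below `min_kmer_count`
   removed, unitigs (maximal non-branching paths) emitted as contigs in
   canonical orientation with deterministic ids.
4. **Filter and iterate** (`run_genefish()`). Contigs are scored against the
   *original* query — never against intermediate contigs, which prevents
   drift — and the best `keep_top_contigs` survivors become the next
   iteration's search queries (in DNA mode: they are now library-identical
   sequence, so later iterations extend by exact overlap). The loop stops at
   the first of: no hits or no kept contigs (`no_hits`; kept contigs of an
   earlier iteration are returned as a partial result), identical contig
   multiset across consecutive iterations (`converged`), a contig whose
   alignments reach both ends of the query (`autocomplete`, optional), or
   the iteration cap.
5. **Validation** (`contig_stats()`, `reciprocal_best_hit()`,
   `alignment_pipeline()`). Percent coverage of a reference, uncorrected
   p-distance over comparable (non-gap, unambiguous) sites, and a
   reciprocal best-hit orthology test of each contig against the whole
   reference protein set. The alignment pipeline stacks each sample's
   passing contig on reference coordinates into one gapped FASTA per locus.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `seed_length` | 12 nt / 4 aa | residues | word size below which exact seeds appear by chance too often; 12 nt matches classic nucleotide search word sizes, 4 aa keeps sensitivity at high amino-acid divergence |
| `min_score` | 40 (DNA), 35 (protein) | raw score | read-versus-query acceptance; ~8 matched bases or ~7 good residues |
| `top_n_per_shard` | 100 | hits | caps pool growth per query per shard; ties broken by fragment id |
| `match/mismatch` | +5/−4 | score | classic nucleotide scoring |
| `gap_open/gap_extend` | −16/−4 (DNA search), −20/−1 (metrics), −8/−2 (protein) | score | see "Scoring regimes" below |
| `k` | 31 | nt | de Bruijn k-mer size, about a third of a 100-base read; must be odd so no k-mer is its own reverse complement |
| `min_kmer_count` | 2 | count | removes singleton error k-mers; use 1 for error-free fixtures and 3 for ≥40× libraries at ~0.5% error, where recurrent same-base errors start to reach count 2 (Poisson math: at 28× k-mer depth a true 31-mer misses count 3 with probability ~1e−8, while count-2 error branches arise at ~0.3% of positions — enough to fragment a 2 kb locus several times) |
| `min_contig_length` | 100 | nt | contigs below one read length carry no assembly evidence |
| `max_iterations` | 5 | — | iteration 0 (the query search) counts as the first |
| `keep_top_contigs` | 5 | contigs | next iteration's query set |
| `contig_min_score` | 100 | raw score | above the expected best random +5/−4 local alignment score (~80) at kb-scale contig/query sizes, below any real exon of ≥ 20 aligned bases |
| `end_window_fraction` | 0.05 | fraction of query | width of the terminal windows the autocomplete test must reach |
| `fraction` | 1.0 | fraction of shards | effective-coverage downsampling; assembly works from roughly 5× and is comfortable at 20–50× |

## Scoring regimes

Two different jobs place two different demands on gap penalties.

**Search and contig filtering** make accept/reject decisions against fixed
raw-score thresholds, which is only sound in the logarithmic
(Karlin–Altschul) regime where the best random local alignment score grows
like `log(nm)`. We measured that +5/−4 with gaps costing `8 + 2L` is *not*
in that regime: optimal local scores of unrelated random pairs grow linearly
(roughly one point per base), so every fixed threshold is eventually crossed
by noise. With `16 + 4L` gaps, random scores stay logarithmic (~60–80 at kb
scale), so the package uses −16/−4 for DNA search scoring and sets
`contig_min_score` at 100, above the random ceiling.

**Metric alignments** (`semi_global_align()`, `percent_coverage()`,
p-distance, alignment stacking) compare an intron-bearing contig with a
spliced, exon-only reference, so they must cross multi-hundred-base
insertions. `metric_scheme()` therefore prices gaps at `21 + L`: opening is
expensive, extension nearly free, an intron becomes one affordable gap —
while a gap-then-match detour through random sequence is still net negative
(≥ 21 against +5), so coverage is not inflated by spurious rescues.

## Numerical and design choices

- **Seed extension** is an exact banded computation: a full affine local DP
  over the query window spanning the seed diagonals, with the (short)
  subject included whole. Its score never exceeds the unconstrained
  Smith–Waterman optimum and equals it whenever an exact seed lies inside
  the optimal alignment — the property the oracle tests assert. An X-drop
  heuristic would be faster on megabase queries but is unnecessary at the
  window sizes involved here, and the exact version is easier to verify.
- **The read pool accumulates across iterations**, and already-pooled
  fragments are excluded from ranking before the per-query top-N cut.
  Re-retrieving a read cannot lose it, so target coverage of the best
  contig is non-decreasing, and each iteration's retrieval quota goes
  entirely to *new* reads. Without the exclusion, full-overlap reads
  dominate the score ranking every round and the low-scoring reads that
  hang off the contig ends — precisely the ones that extend the assembly —
  are truncated away, slowing growth to roughly one insert length per
  iteration per flank.
- **Autocomplete uses the union of a contig's local alignments** to the
  query (per orientation for DNA, per translated frame for proteins).
  A single local alignment cannot span an intron — crossing several hundred
  inserted bases costs far more than any terminal exon gains — so requiring
  one spanning alignment would never fire on spliced queries. The union
  fires as soon as *some* exon alignment reaches each terminal window.
  Queries whose terminal exons are very short remain the known failure mode
  and may run to the iteration cap with the locus in fact complete.
- **Ties everywhere break deterministically**: hits by fragment id, contigs
  by length then sequence, traceback by match > gap-in-first-sequence >
  gap-in-second. Identical inputs reproduce byte-identical outputs,
  including the on-disk database layout.
- **Orientation is canonicalized** (a sequence and its reverse complement
  are interchangeable, represented by the lexicographic minimum), which
  makes contig-set convergence well defined on strand-ambiguous data.
- Coordinates are 1-based inclusive in R structures (exon tables); alignment
  spans in hit tables are 0-based half-open, matching the on-disk trace
  format; shard indices are 0-based and match the shard file names.

## What the simulator emulates — and what it does not

`simulate_genome()` produces a uniform-random background with
non-overlapping, flanked, intron-bearing genes whose concatenated exons form
stop-free coding sequence on either strand. `simulate_paired_reads()` draws
fragments with Normal insert lengths, takes the 5′ read and the reverse
complement of the 3′ end, and applies i.i.d. per-base substitution errors.
`mutate_homolog()` applies i.i.d. substitutions at a chosen per-site
divergence.

Deliberately absent: indels (in errors and in evolution), quality-dependent
and GC-biased error profiles, repeat families, paralogy beyond what the
tests construct explicitly, and rate heterogeneity across sites (real
coding sequence concentrates divergence in synonymous positions; the
simulator spreads it uniformly). Consequences worth knowing:

- Passing the reconstruction tests shows the assembler is exact on
  substitution-only data; it says nothing about indel-rich or repeat-rich
  loci, where the no-bubble-popping design will fragment contigs.
- Under uniform substitution-only divergence of 20%, a 100-base read still
  contains a conserved 12-mer with probability ~0.7, so DNA queries keep
  finding diverged loci in these simulations. On real divergent taxa DNA
  queries fail much earlier (indels break seeds, synonymous saturation
  pushes local nucleotide divergence far above the average). The package's
  divergent-taxon simulations therefore *understate* the advantage of
  protein queries; protein queries are the recommended choice for anything
  beyond congeners either way.

## Problem sizes used by the test suite

The acceptance harness simulates a 100 kb genome with 10 intron-bearing
genes (2–4 exons of 150–300 bp, introns 50–500 bp, 500 bp flanks), read
libraries at 30× (error-free) and 40× (0.5% error), homologs at 10% and 20%
nucleotide divergence, a 50-gene single-exon proteome for the orthology
sweep, and 10,000 pairs across 8 shards for the balance contract — sizes at
which every property is exercised end-to-end in a couple of minutes on one
core. The oracle-equivalence suites run 100 seeded trials each against
independent reference implementations (Biostrings alignments).

## Known limitations

- The internal assembler performs no bubble popping, tip clipping or
  paired-end scaffolding; `min_kmer_count` is the only error control. For
  locus-restricted pools this is usually enough; heavier assembly belongs in
  plugin backends (`register_assembler()`).
- Raw-score thresholds, not E-values: deterministic and database-size
  independent, but not comparable across scoring schemes.
- Shards are held in memory once loaded; the on-disk layout is plain TSV.
  Desk-scale libraries (up to a few million pairs) are the design point.
- Multi-library co-assembly and RNA-seq-specific handling are out of scope.
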