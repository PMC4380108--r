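# Simulator of intron-bearing genomes, diverged homolog genomes, and
# paired-end read libraries. Substitution-only error and divergence models
# keep the assembler's reconstruction properties exact; indels are not
# simulated. Everything is deterministic given its seed (the global RNG
# state is left untouched).

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# the 61 sense codons: simulated coding sequence is stop-free in frame
sense_codons <- function() {
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

rand_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Simulate a genome with intron-bearing protein-coding genes
#'
#' A uniform random background sequence with `n_genes` non-overlapping genes,
#' each at least `flank` bases from its neighbours and the sequence ends.
#' Exons are separated by introns of 50-500 bases; the concatenated exon
#' length of every gene is a multiple of 3 (it codes a protein). Strands are
#' drawn at random.
#'
#' @param length Genome length in bases.
#' @param n_genes Number of genes (0 gives a pure random sequence).
#' @param exons_per_gene Integer range sampled per gene, e.g. `2:4`.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param exon_bp,intron_bp Length ranges (min, max) for exons and introns.
#' @param flank Minimum distance between genes and from the sequence ends.
#' @return A `genefish_genome`: `seq`, `genes` (tibble `gene_id`, `strand`,
#'   `exons` list-column of tibbles with 1-based inclusive `start`/`end`),
#'   `seed`.
#' @export
simulate_genome <- function(length, n_genes, exons_per_gene = 2:4, seed = 1,
                            exon_bp = c(150, 300), intron_bp = c(50, 500),
                            flank = 500) {
  withr::with_seed(seed, {
    genes <- list()
    spans <- integer(n_genes)
    structures <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      ne <- if (base::length(exons_per_gene) == 1L) exons_per_gene
            else sample(exons_per_gene, 1L)
      ex <- sample(exon_bp[1]:exon_bp[2], ne, replace = TRUE)
      extra <- sum(ex) %% 3L
      ex[ne] <- ex[ne] - extra  # coding length divisible by 3
      intr <- if (ne > 1L) sample(intron_bp[1]:intron_bp[2], ne - 1L, replace = TRUE)
              else integer()
      structures[[g]] <- list(ex = ex, intr = intr)
      spans[g] <- sum(ex) + sum(intr)
    }
    needed <- sum(spans) + (n_genes + 1L) * flank
    if (n_genes > 0 && needed > length)
      stop("genome of ", length, " bases cannot fit ", n_genes,
           " genes with ", flank, "-base flanks (needs >= ", needed, ")")
    seq <- rand_dna(length)
    gene_rows <- list()
    if (n_genes > 0) {
      slack <- length - needed
      cuts <- sort(sample.int(slack + 1L, n_genes, replace = TRUE) - 1L)
      starts <- integer(n_genes)
      pos <- 0L
      for (g in seq_len(n_genes)) {
        extra_gap <- cuts[g] - (if (g > 1L) cuts[g - 1L] else 0L)
        starts[g] <- pos + flank + extra_gap + 1L
        pos <- starts[g] + spans[g] - 1L
      }
      for (g in seq_len(n_genes)) {
        st <- structures[[g]]
        ne <- base::length(st$ex)
        es <- integer(ne)
        ee <- integer(ne)
        p <- starts[g]
        for (e in seq_len(ne)) {
          es[e] <- p
          ee[e] <- p + st$ex[e] - 1L
          p <- ee[e] + (if (e < ne) st$intr[e] else 0L) + 1L
        }
        strand <- sample(c("+", "-"), 1L)
        # overwrite exonic positions with stop-free coding sequence so the
        # gene really encodes a protein
        cds <- rand_cds(sum(st$ex) %/% 3L)
        genomic <- if (strand == "+") cds else as.character(cpp_revcomp(cds))
        off <- 0L
        for (e in seq_len(ne)) {
          substr(seq, es[e], ee[e]) <- substr(genomic, off + 1L, off + st$ex[e])
          off <- off + st$ex[e]
        }
        gene_rows[[g]] <- tibble(
          gene_id = sprintf("gene%02d", g),
          strand = strand,
          exons = list(tibble(start = es, end = ee)))
      }
    }
    genes_tbl <- if (base::length(gene_rows)) bind_rows(gene_rows)
                 else tibble(gene_id = character(), strand = character(),
                             exons = list())
    structure(list(seq = seq, genes = genes_tbl, seed = seed),
              class = "genefish_genome")
  })
}

#' @export
print.genefish_genome <- function(x, ...) {
  cat("<genefish_genome> ", nchar(x$seq), " bp, ", nrow(x$genes), " gene(s)\n",
      sep = "")
  invisible(x)
}

#' Spliced coding sequence of a simulated gene
#'
#' Concatenated exons, reverse-complemented for minus-strand genes.
#' @param genome A `genefish_genome`.
#' @param gene_id Gene id.
#' @return A single DNA string.
#' @export
gene_cds <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("no such gene: ", gene_id)
  ex <- genome$genes$exons[[i]]
  cds <- paste(substring(genome$seq, ex$start, ex$end), collapse = "")
  if (genome$genes$strand[i] == "-") cds <- as.character(cpp_revcomp(cds)) else cds
}

#' Protein sequence of a simulated gene
#'
#' Frame-0 translation of [gene_cds()], without a trailing stop symbol.
#' @inheritParams gene_cds
#' @return A single amino-acid string.
#' @export
gene_protein <- function(genome, gene_id) {
  aa <- translate_six_frames(gene_cds(genome, gene_id))[1]
  sub("\\*$", "", aa)
}

#' Genomic span of a simulated gene (introns included)
#'
#' @inheritParams gene_cds
#' @return A single DNA string from the first to the last exonic base.
#' @export
gene_locus <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("no such gene: ", gene_id)
  ex <- genome$genes$exons[[i]]
  substring(genome$seq, min(ex$start), max(ex$end))
}

#' Simulate a diverged homolog of a genome
#'
#' Substitutes each position independently with probability `nt_divergence`
#' (to a uniformly chosen different base). Gene coordinates are preserved;
#' with substitutions only, reading-frame lengths are automatically
#' preserved too.
#'
#' @param genome A `genefish_genome`.
#' @param nt_divergence Per-site substitution probability in `[0, 0.75)`.
#' @param seed Integer seed.
#' @return A new `genefish_genome` with the same gene annotation.
#' @export
mutate_homolog <- function(genome, nt_divergence, seed = 1) {
  stopifnot(nt_divergence >= 0, nt_divergence < 0.75)
  mutated <- withr::with_seed(seed, cpp_mutate(genome$seq, nt_divergence))
  structure(list(seq = as.character(mutated), genes = genome$genes, seed = seed),
            class = "genefish_genome")
}

#' Simulate a paired-end read library
#'
#' Fragments have Normal(`insert_mean`, `insert_sd`) lengths (truncated to at
#' least `read_length`) and uniform start positions; read 1 is the fragment's
#' 5' end and read 2 the reverse complement of its 3' end. Substitution
#' errors are i.i.d. per base. The number of pairs is
#' `round(coverage * genome_length / (2 * read_length))`. Uniform qualities
#' (`I` = Q40) are emitted so pairs are FASTQ-writable.
#'
#' @param genome A `genefish_genome` (or a bare DNA string).
#' @param read_length,insert_mean,insert_sd,coverage,error_rate Library
#'   parameters; overlapping pairs (insert < 2 * read_length) are allowed.
#' @param seed Integer seed.
#' @return A pair tibble as accepted by [build_db()].
#' @export
simulate_paired_reads <- function(genome, read_length = 100, insert_mean = 300,
                                  insert_sd = 30, coverage = 30,
                                  error_rate = 0.005, seed = 1) {
  seq <- if (inherits(genome, "genefish_genome")) genome$seq else genome
  L <- nchar(seq)
  stopifnot(read_length <= L, coverage > 0)
  n <- round(coverage * L / (2 * read_length))
  withr::with_seed(seed, {
    frag <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), read_length), L)
    start <- floor(runif(n, min = 1, max = L - frag + 1 + 1))
    r1 <- substring(seq, start, start + read_length - 1L)
    r2 <- as.character(cpp_revcomp(substring(seq, start + frag - read_length,
                                             start + frag - 1L)))
    if (error_rate > 0) {
      r1 <- as.character(cpp_mutate(r1, error_rate))
      r2 <- as.character(cpp_mutate(r2, error_rate))
    }
    pid <- sprintf("frag%07d", seq_len(n))
    tibble(pair_id = pid,
           id1 = paste0(pid, "/1"), seq1 = r1, qual1 = strrep("I", read_length),
           id2 = paste0(pid, "/2"), seq2 = r2, qual2 = strrep("I", read_length))
  })
}

#' Write a truth table of simulated gene structures
#'
#' One row per exon: `gene_id`, `strand`, `exon`, `start`, `end` (1-based
#' inclusive).
#' @param genome A `genefish_genome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(genome, path) {
  rows <- lapply(seq_len(nrow(genome$genes)), function(i) {
    ex <- genome$genes$exons[[i]]
    tibble(gene_id = genome$genes$gene_id[i], strand = genome$genes$strand[i],
           exon = seq_len(nrow(ex)), start = ex$start, end = ex$end)
  })
  tbl <- if (length(rows)) bind_rows(rows) else
    tibble(gene_id = character(), strand = character(), exon = integer(),
           start = integer(), end = integer())
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
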