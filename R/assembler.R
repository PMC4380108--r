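# Built-in de Bruijn graph assembler. Nodes are canonical k-mers (the
# lexicographic minimum of a k-mer and its reverse complement), edges are
# (k-1)-overlaps, and contigs are maximal non-branching paths (unitigs).
# There is no bubble popping or scaffolding: pools are small and
# locus-restricted, and count filtering is the only error removal. Heavier
# assembly belongs to plugin backends.

#' Assembly parameters
#'
#' @param k Odd k-mer size in `[15, 31]`. The default 31 is roughly a third
#'   of a typical 100-base read, the same read-length-relative regime as
#'   classic short-read de novo assemblies.
#' @param min_kmer_count Minimum count for a k-mer to enter the graph. Use 1
#'   for error-free fixtures; the default 2 suppresses singleton sequencing
#'   errors; 3 is recommended at >= 40x coverage with ~0.5% error, where
#'   recurrent same-base errors start producing count-2 branch points.
#' @param min_contig_length Contigs shorter than this are dropped.
#' @return A `genefish_assembly_params` list.
#' @export
assembly_params <- function(k = 31, min_kmer_count = 2, min_contig_length = 100) {
  if (k < 15 || k > 31 || k %% 2 == 0) stop("k must be odd and in [15, 31]")
  if (min_kmer_count < 1) stop("min_kmer_count must be >= 1")
  structure(list(k = as.integer(k), min_kmer_count = as.integer(min_kmer_count),
                 min_contig_length = as.integer(min_contig_length)),
            class = "genefish_assembly_params")
}

#' Build the de Bruijn graph of a read set
#'
#' Counts canonical k-mers over both strands of all reads (k-mers containing
#' non-ACGT symbols are skipped), removes k-mers below `min_kmer_count`, and
#' returns the surviving nodes. Edges are implicit (k-1)-overlaps.
#'
#' @param reads Character vector of DNA reads, or a tibble with a `seq`
#'   column.
#' @param params An [assembly_params()].
#' @return A `genefish_graph`: list with `kmer` (canonical k-mer strings,
#'   sorted), `count`, and `k`.
#' @export
build_debruijn <- function(reads, params = assembly_params()) {
  if (is.data.frame(reads)) reads <- reads$seq
  g <- cpp_kmer_count(normalize_dna(reads), params$k, params$min_kmer_count)
  structure(list(kmer = g$kmer, count = g$count, k = params$k),
            class = "genefish_graph")
}

#' @export
print.genefish_graph <- function(x, ...) {
  cat("<genefish_graph> ", length(x$kmer), " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Extract contigs (unitigs) from a de Bruijn graph
#'
#' Maximal non-branching paths are emitted as sequences in canonical
#' orientation, with the mean node count along the path as k-mer coverage.
#' Contig ids are `c<rank>` with ranks by decreasing length (ties by sequence,
#' byte order), so output is deterministic for a given read multiset.
#'
#' @param graph A `genefish_graph` from [build_debruijn()].
#' @param params The [assembly_params()] of the run (for
#'   `min_contig_length`).
#' @return Contig tibble: `contig_id`, `seq`, `length`, `mean_kmer_coverage`.
#' @export
extract_contigs <- function(graph, params = assembly_params()) {
  stopifnot(inherits(graph, "genefish_graph"))
  u <- cpp_unitigs(graph$kmer, graph$count, graph$k, params$min_contig_length)
  res <- tibble(seq = as.character(u$seq),
                length = nchar(as.character(u$seq)),
                mean_kmer_coverage = as.numeric(u$mean_cov))
  res <- res[order(-res$length, res$seq, method = "radix"), ]
  res$contig_id <- paste0("c", seq_len(nrow(res)))
  res[, c("contig_id", "seq", "length", "mean_kmer_coverage")]
}

the_backends <- new.env(parent = emptyenv())

#' Register a plugin assembler backend
#'
#' A backend is a function `function(reads, params)` returning a contig
#' tibble with the same columns as [extract_contigs()]. Plugins must be
#' deterministic given their seed to honor the reproducibility contract.
#'
#' @param name Backend name used in `assemble_reads(backend = )`.
#' @param fun The backend function.
#' @export
register_assembler <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  the_backends[[name]] <- fun
  invisible(name)
}

#' Assemble a read pool into contigs
#'
#' The internal backend is [build_debruijn()] followed by
#' [extract_contigs()]. Plugin backends registered with
#' [register_assembler()] satisfy the same signature and determinism
#' contract.
#'
#' @param reads Character vector of DNA reads or tibble with `seq`.
#' @param params An [assembly_params()].
#' @param backend `"internal"` or a registered plugin name.
#' @return Contig tibble: `contig_id`, `seq`, `length`, `mean_kmer_coverage`.
#' @export
assemble_reads <- function(reads, params = assembly_params(), backend = "internal") {
  if (identical(backend, "internal"))
    return(extract_contigs(build_debruijn(reads, params), params))
  fun <- the_backends[[backend]]
  if (is.null(fun)) stop("unknown assembler backend: '", backend, "'")
  fun(reads, params)
}
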