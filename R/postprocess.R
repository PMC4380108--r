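# Validation metrics: overlap (semi-global) pairwise alignment, uncorrected
# p-distance, percent coverage of a reference, and the reciprocal best-hit
# orthology test of a contig against a reference protein set.

#' Insertion-tolerant scheme for metric alignments
#'
#' Contigs carry introns that a spliced (exon-only) reference lacks, so the
#' metric alignments must cross multi-hundred-base insertions: gap opening is
#' expensive (-20) but extension cheap (-1), making an intron a single
#' affordable gap while any gap-then-match detour through random sequence
#' stays net negative (21 + L against +5). Search scoring, where fixed score
#' thresholds must separate homology from noise, uses
#' [scoring_scheme()]'s stricter defaults instead.
#'
#' @param ... Overrides passed to [scoring_scheme()].
#' @return A DNA `genefish_scheme`.
#' @export
metric_scheme <- function(...) {
  scoring_scheme("dna", gap_open = -20, gap_extend = -1, ...)
}

count_sites <- function(a, b, mode) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- if (mode == "dna") c("A", "C", "G", "T") else setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  comparable <- ca %in% ok & cb %in% ok
  list(comparable = sum(comparable),
       differing = sum(comparable & ca != cb))
}

#' Overlap (semi-global) pairwise alignment
#'
#' Optimal affine-gap alignment with free end gaps on both sequences;
#' unaligned overhangs appear as gap-padded columns. Traceback ties prefer
#' match/mismatch over a gap in `a` over a gap in `b`, so output is
#' deterministic. Columns containing a gap or an ambiguity symbol in either
#' row are excluded from the comparable-site counts.
#'
#' @param a,b Sequences (same alphabet as `scheme`).
#' @param scheme A [scoring_scheme()].
#' @return A `genefish_alignment`: `a`, `b` (equal-length gapped strings),
#'   `score`, `comparable_sites`, `differing_sites`, `mode`.
#' @export
semi_global_align <- function(a, b, scheme = metric_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  a <- toupper(a)
  b <- toupper(b)
  if (scheme$mode == "dna") { a <- normalize_dna(a); b <- normalize_dna(b) }
  al <- cpp_overlap_align(a, b, scheme_c(scheme))
  sites <- count_sites(al$a, al$b, scheme$mode)
  structure(list(a = al$a, b = al$b, score = al$score,
                 comparable_sites = sites$comparable,
                 differing_sites = sites$differing, mode = scheme$mode),
            class = "genefish_alignment")
}

#' @export
print.genefish_alignment <- function(x, ...) {
  cat("<genefish_alignment> score ", x$score, ", ", x$comparable_sites,
      " comparable sites, ", x$differing_sites, " differing\n", sep = "")
  invisible(x)
}

#' Uncorrected p-distance of an aligned pair
#'
#' The proportion of differing sites among comparable sites (columns where
#' both rows hold an unambiguous residue), with no substitution-model
#' correction. `NA` when no sites are comparable.
#'
#' @param pair A `genefish_alignment` from [semi_global_align()], or a
#'   two-element character vector of equal-length gapped strings (assumed
#'   DNA).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @examples
#' p_distance(c("AC-GT", "ACTGA"))
#' @export
p_distance <- function(pair) {
  if (inherits(pair, "genefish_alignment")) {
    comparable <- pair$comparable_sites
    differing <- pair$differing_sites
  } else {
    stopifnot(is.character(pair), length(pair) == 2L,
              nchar(pair[1]) == nchar(pair[2]))
    s <- count_sites(toupper(pair[1]), toupper(pair[2]), "dna")
    comparable <- s$comparable
    differing <- s$differing
  }
  if (comparable == 0) return(NA_real_)
  differing / comparable
}

#' Fraction of a reference covered by a contig
#'
#' Aligns the contig to the reference in both orientations (the
#' better-scoring orientation wins; ties prefer forward) and reports the
#' fraction of reference positions aligned to a non-gap contig symbol.
#'
#' @param contig Contig sequence (string or one-row tibble).
#' @param reference Reference sequence (string or one-row tibble).
#' @param scheme A DNA [scoring_scheme()].
#' @return A number in `[0, 1]`.
#' @export
percent_coverage <- function(contig, reference, scheme = metric_scheme()) {
  if (is.data.frame(contig)) contig <- contig$seq[1]
  if (is.data.frame(reference)) reference <- reference$seq[1]
  stopifnot(scheme$mode == "dna")
  fwd <- semi_global_align(reference, contig, scheme)
  rev <- semi_global_align(reference, cpp_revcomp(normalize_dna(toupper(contig))), scheme)
  al <- if (rev$score > fwd$score) rev else fwd
  ra <- strsplit(al$a, "", fixed = TRUE)[[1]]
  rb <- strsplit(al$b, "", fixed = TRUE)[[1]]
  covered <- sum(ra != "-" & rb != "-")
  covered / nchar(gsub("-", "", al$a, fixed = TRUE))
}

#' Reciprocal best-hit orthology test
#'
#' The six translated frames of a contig are searched against every protein
#' of a reference set; the contig is called orthologous to its query gene iff
#' that gene is the highest-scoring reference protein (score ties broken by
#' id, ascending).
#'
#' @param contig Contig sequence (string or one-row tibble with
#'   `contig_id`/`seq`).
#' @param query_gene_id Id of the gene the contig was assembled for; must be
#'   present in `reference_proteome`.
#' @param reference_proteome Tibble (`id`, `seq`) of reference proteins.
#' @param scheme A protein [scoring_scheme()].
#' @param params A [search_params()] (protein defaults apply).
#' @return One-row tibble: `contig_id`, `query_gene_id`,
#'   `best_reference_hit`, `best_score`, `is_ortholog`.
#' @export
reciprocal_best_hit <- function(contig, query_gene_id, reference_proteome,
                                scheme = scoring_scheme("protein"),
                                params = search_params()) {
  contig_id <- "contig"
  if (is.data.frame(contig)) {
    if ("contig_id" %in% names(contig)) contig_id <- contig$contig_id[1]
    contig <- contig$seq[1]
  }
  stopifnot(scheme$mode == "protein")
  if (!query_gene_id %in% reference_proteome$id)
    stop("query gene '", query_gene_id, "' is absent from the reference proteome")
  params <- resolve_search(params, "protein")
  frames <- unlist(lapply(cpp_translate6(normalize_dna(toupper(contig))), `[[`, 1L))
  frames <- frames[nzchar(frames)]
  best <- rep(0L, nrow(reference_proteome))
  sc <- scheme_c(scheme)
  for (f in frames) {
    h <- cpp_search(f, toupper(reference_proteome$seq), sc,
                    params$seed_length, 1L)
    if (nrow(h)) best[h$idx] <- pmax(best[h$idx], h$score)
  }
  ord <- order(-best, reference_proteome$id, method = "radix")
  top <- ord[1]
  hit_id <- if (best[top] > 0L) reference_proteome$id[top] else NA_character_
  tibble(contig_id = contig_id, query_gene_id = query_gene_id,
         best_reference_hit = hit_id, best_score = best[top],
         is_ortholog = identical(hit_id, query_gene_id))
}

#' Validation statistics for a set of contigs
#'
#' Per contig: percent coverage of its reference, uncorrected p-distance over
#' the aligned comparable sites, and (when a proteome is given) the
#' reciprocal best-hit orthology call.
#'
#' @param contigs Contig tibble (`contig_id`, `seq`) with a `reference_id`
#'   column naming the reference (and query gene) of each contig, or a single
#'   shared `reference_id` argument.
#' @param references Tibble (`id`, `seq`) of DNA reference sequences.
#' @param proteome Optional tibble (`id`, `seq`) of reference proteins for
#'   the orthology test.
#' @param reference_id Used when `contigs` has no `reference_id` column.
#' @return Tibble: `contig_id`, `reference_id`, `percent_coverage`,
#'   `p_distance`, `best_reference_hit`, `is_ortholog`.
#' @export
contig_stats <- function(contigs, references, proteome = NULL, reference_id = NULL) {
  stopifnot(is.data.frame(contigs), is.data.frame(references))
  if (!"reference_id" %in% names(contigs)) {
    if (is.null(reference_id)) stop("need a reference_id per contig")
    contigs$reference_id <- reference_id
  }
  dna <- metric_scheme()
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    rid <- contigs$reference_id[i]
    ref <- references$seq[match(rid, references$id)]
    if (is.na(ref)) stop("reference '", rid, "' not found")
    cseq <- contigs$seq[i]
    fwd <- semi_global_align(ref, cseq, dna)
    rev <- semi_global_align(ref, cpp_revcomp(normalize_dna(toupper(cseq))), dna)
    al <- if (rev$score > fwd$score) rev else fwd
    cov <- percent_coverage(cseq, ref, dna)
    rbh <- if (!is.null(proteome) && rid %in% proteome$id)
      reciprocal_best_hit(contigs[i, ], rid, proteome) else NULL
    tibble(contig_id = contigs$contig_id[i], reference_id = rid,
           percent_coverage = cov, p_distance = p_distance(al),
           best_reference_hit = if (is.null(rbh)) NA_character_ else rbh$best_reference_hit,
           is_ortholog = if (is.null(rbh)) NA else rbh$is_ortholog)
  })
  bind_rows(rows)
}
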