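# The iterative targeted-assembly loop. Iteration 0 searches the shards with
# the user's DNA or protein query; every later iteration searches with the
# previous iteration's kept contigs (always in DNA mode, since contigs are
# nucleotide sequence assembled from the library itself). After each
# assembly, contigs are scored against the ORIGINAL query - never against
# intermediate contigs - which anchors the locus and prevents drift. The
# retrieved read pool accumulates across iterations, so the assembly input
# only grows and coverage of the target is non-decreasing.

#' Parameters of the iterative assembly loop
#'
#' @param max_iterations Maximum number of search/assemble cycles; iteration
#'   0 (the query search) counts as the first.
#' @param fraction Fraction of shards to search, in (0, 1].
#' @param autocomplete Stop as soon as a kept contig aligns into both
#'   terminal windows of the query (the locus is presumed complete).
#' @param search A [search_params()].
#' @param assembly An [assembly_params()].
#' @param keep_top_contigs Contigs kept per iteration after scoring against
#'   the query.
#' @param contig_min_score Minimum alignment score against the query for a
#'   contig to be kept. The default 100 sits above the Karlin-Altschul
#'   expected maximum of random +5/-4 local alignments at kb contig/query
#'   sizes (about 80), so unrelated contigs are dropped while any real exon
#'   of >= 20 aligned bases passes.
#' @param end_window_fraction Width of each terminal query window used by the
#'   autocomplete test, as a fraction of query length (in (0, 0.5]). The
#'   alignments of a contig to the query are unioned, so a query whose ends
#'   fall in different exons of the contig still completes.
#' @return A `genefish_params` list.
#' @export
genefish_params <- function(max_iterations = 5, fraction = 1, autocomplete = FALSE,
                         search = search_params(), assembly = assembly_params(),
                         keep_top_contigs = 5, contig_min_score = 100,
                         end_window_fraction = 0.05) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (end_window_fraction <= 0 || end_window_fraction > 0.5)
    stop("end_window_fraction must be in (0, 0.5]")
  structure(list(max_iterations = as.integer(max_iterations), fraction = fraction,
                 autocomplete = isTRUE(autocomplete), search = search,
                 assembly = assembly,
                 keep_top_contigs = as.integer(keep_top_contigs),
                 contig_min_score = as.integer(contig_min_score),
                 end_window_fraction = end_window_fraction),
            class = "genefish_params")
}

# best alignment score of one contig against the original target
contig_target_score <- function(contig_seq, target_seq, scheme, seed_length) {
  if (scheme$mode == "dna") {
    best <- 0L
    for (s in c(contig_seq, cpp_revcomp(contig_seq))) {
      h <- seed_and_extend(target_seq, s, scheme, seed_length)
      if (!is.null(h)) best <- max(best, h$score)
    }
    best
  } else {
    frames <- unlist(lapply(cpp_translate6(contig_seq), `[[`, 1L))
    best <- 0L
    for (f in frames) {
      if (!nzchar(f)) next
      h <- seed_and_extend(target_seq, f, scheme, seed_length)
      if (!is.null(h)) best <- max(best, h$score)
    }
    best
  }
}

#' Score contigs against the original target and keep the best
#'
#' Each contig is aligned to the original query (protein queries against the
#' six translated frames of the contig, best frame kept; DNA queries against
#' both contig orientations). Contigs under `contig_min_score` are dropped;
#' survivors are sorted by score (ties by contig id) and truncated to
#' `keep_top_contigs`.
#'
#' @param contigs Contig tibble from [assemble_reads()].
#' @param target One-row target tibble or a single sequence string.
#' @param scheme [scoring_scheme()] matching the target alphabet.
#' @param params [genefish_params()].
#' @return The kept contigs with a `score` column.
#' @export
score_contigs_vs_target <- function(contigs, target, scheme, params = genefish_params()) {
  if (is.data.frame(target)) target <- target$seq[1]
  if (nrow(contigs) == 0) {
    contigs$score <- integer()
    return(contigs)
  }
  sp <- resolve_search(params$search, scheme$mode)
  contigs$score <- vapply(contigs$seq, contig_target_score, integer(1),
                          target_seq = target, scheme = scheme,
                          seed_length = sp$seed_length, USE.NAMES = FALSE)
  contigs <- contigs[contigs$score >= params$contig_min_score, ]
  contigs <- contigs[order(-contigs$score, contigs$contig_id, method = "radix"), ]
  head(contigs, params$keep_top_contigs)
}

# union of the query spans of all HSPs of target vs contig
target_span_union <- function(contig_seq, target_seq, scheme, min_score) {
  spans <- NULL
  if (scheme$mode == "dna") {
    subjects <- c(contig_seq, cpp_revcomp(contig_seq))
  } else {
    subjects <- unlist(lapply(cpp_translate6(contig_seq), `[[`, 1L))
    subjects <- subjects[nzchar(subjects)]
  }
  out <- list()
  for (s in subjects) {
    h <- local_hsps(target_seq, s, scheme, min_score)
    if (nrow(h)) out[[length(out) + 1L]] <- h[, c("q0", "q1")]
  }
  if (length(out)) bind_rows(out) else tibble(q0 = integer(), q1 = integer())
}

#' Does a contig reach both ends of the query?
#'
#' True when the union of the contig's local alignments to the query covers
#' at least one position inside the first terminal window and one inside the
#' last terminal window of the query (window width =
#' `end_window_fraction * query length`). Protein queries are matched against
#' the contig's translated frames, so ends lying in different exons still
#' count.
#'
#' @param contig One-row contig tibble or sequence string.
#' @param target One-row target tibble or sequence string.
#' @param scheme [scoring_scheme()] for the target alphabet.
#' @param params [genefish_params()].
#' @return Logical.
#' @export
check_autocomplete <- function(contig, target, scheme, params = genefish_params()) {
  if (is.data.frame(contig)) contig <- contig$seq[1]
  if (is.data.frame(target)) target <- target$seq[1]
  L <- nchar(target)
  w <- ceiling(params$end_window_fraction * L)
  spans <- target_span_union(contig, target, scheme, params$contig_min_score)
  if (nrow(spans) == 0) return(FALSE)
  any(spans$q0 < w) && any(spans$q1 > L - w)
}

#' Have the contigs converged?
#'
#' True when the multisets of canonical-orientation contig sequences of two
#' iterations are equal; ids and order are ignored.
#'
#' @param current,previous Contig tibbles.
#' @return Logical.
#' @export
converged <- function(current, previous) {
  identical(sort(canonical_seq(current$seq)), sort(canonical_seq(previous$seq)))
}

#' Iteratively assemble one target locus from a sharded read database
#'
#' Runs the full search/assemble loop for one DNA or protein query: search
#' the shards, pool top hits with their mates, assemble, keep the contigs
#' most similar to the query, and repeat with those contigs as queries. The
#' loop ends at the first of: no hits / no kept contigs (`no_hits`; kept
#' contigs of an earlier iteration, if any, are returned as the final,
#' partial assembly), contig-set convergence (`converged`), the autocomplete
#' test firing (`autocomplete`, only when `params$autocomplete` is set), or
#' the iteration cap (`max_iterations`).
#'
#' @param db A `genefish_db`.
#' @param target One-row tibble (`id`, `seq`) or named character of length 1.
#'   A protein sequence forces protein-mode search at iteration 0.
#' @param params [genefish_params()].
#' @return A `genefish_result`: `target_id`, `final_contigs`, `best_contig`
#'   (one-row tibble or `NULL`), `trace` (list of per-iteration records),
#'   `termination`. See [tidy.genefish_result()] for the tabular trace.
#' @export
run_genefish <- function(db, target, params = genefish_params()) {
  stopifnot(inherits(db, "genefish_db"))
  if (is.character(target)) {
    target <- tibble(id = names(target) %||% "target", seq = unname(target))
  }
  target_id <- target$id[1]
  target_seq <- toupper(target$seq[1])
  mode <- guess_alphabet(target_seq)
  if (mode == "dna") target_seq <- normalize_dna(target_seq)
  target_scheme <- scoring_scheme(mode)
  dna_scheme <- if (mode == "dna") target_scheme else scoring_scheme("dna")
  if (db$total_pairs == 0) stop("empty database")
  search_p <- params$search
  search_p$fraction <- params$fraction
  pool <- NULL
  prev_kept <- NULL
  trace <- list()
  finish <- function(status, contigs, kept, n_hits, n_pool, it) {
    trace[[it + 1L]] <<- list(iteration = it, n_hits = n_hits,
                              n_pairs_in_pool = n_pool, contigs = contigs,
                              kept_contigs = kept, status = status)
    status
  }
  termination <- NULL
  final_kept <- NULL
  for (it in seq_len(params$max_iterations) - 1L) {
    if (it == 0L) {
      queries <- tibble(id = target_id, seq = target_seq)
      scheme_it <- target_scheme
    } else {
      queries <- tibble(id = prev_kept$contig_id, seq = prev_kept$seq)
      scheme_it <- dna_scheme
    }
    new_pool <- gather_read_pool(db, queries, scheme_it, search_p,
                                 exclude_ids = pool$pair_id)
    n_hits <- attr(new_pool, "n_hits")
    pool <- if (is.null(pool)) new_pool else
      distinct(bind_rows(pool, new_pool), .data$pair_id, .keep_all = TRUE)
    if (nrow(pool) == 0) {
      termination <- finish("no_hits", empty_contigs(), empty_contigs(),
                            n_hits, 0L, it)
      final_kept <- empty_contigs()
      break
    }
    reads <- c(pool$seq1, pool$seq2)
    contigs <- assemble_reads(reads, params$assembly)
    kept <- score_contigs_vs_target(contigs, target_seq, target_scheme, params)
    if (nrow(kept) == 0) {
      # partial assembly from an earlier iteration is still a result
      final_kept <- prev_kept %||% empty_contigs()
      termination <- finish("no_hits", contigs, kept, n_hits, nrow(pool), it)
      break
    }
    if (params$autocomplete &&
        any(vapply(kept$seq, check_autocomplete, logical(1),
                   target = target_seq, scheme = target_scheme, params = params))) {
      termination <- finish("autocomplete", contigs, kept, n_hits, nrow(pool), it)
      final_kept <- kept
      break
    }
    if (!is.null(prev_kept) && converged(kept, prev_kept)) {
      termination <- finish("converged", contigs, kept, n_hits, nrow(pool), it)
      final_kept <- kept
      break
    }
    if (it == params$max_iterations - 1L) {
      termination <- finish("max_iterations", contigs, kept, n_hits, nrow(pool), it)
      final_kept <- kept
      break
    }
    finish("continue", contigs, kept, n_hits, nrow(pool), it)
    prev_kept <- kept
  }
  best <- NULL
  if (!is.null(final_kept) && nrow(final_kept) > 0) best <- final_kept[1, ]
  structure(list(target_id = target_id, final_contigs = final_kept,
                 best_contig = best, trace = trace, termination = termination),
            class = "genefish_result")
}

empty_contigs <- function() {
  tibble(contig_id = character(), seq = character(), length = integer(),
         mean_kmer_coverage = numeric(), score = integer())
}

#' @export
print.genefish_result <- function(x, ...) {
  cat("<genefish_result> target '", x$target_id, "': ", x$termination,
      " after ", length(x$trace), " iteration(s)\n", sep = "")
  if (!is.null(x$best_contig))
    cat("  best contig: ", x$best_contig$contig_id, " (", x$best_contig$length,
        " bp, score ", x$best_contig$score, ")\n", sep = "")
  invisible(x)
}
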