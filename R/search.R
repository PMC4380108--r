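# Seed-and-extend local similarity search of a DNA or protein query against
# the reads of a shard. Exact shared words of the seed length nominate
# candidate reads; candidates are extended by exact affine-gap local DP on a
# window of the query around the seed diagonals. Scores are raw alignment
# scores (deterministic and database-size independent), not E-values.

the_blosum_cache <- new.env(parent = emptyenv())

blosum62_star <- function() {
  if (is.null(the_blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    # '*' must mismatch every residue (including itself)
    m["*", ] <- -4L
    m[, "*"] <- -4L
    storage.mode(m) <- "integer"
    the_blosum_cache$m <- m
  }
  the_blosum_cache$m
}

#' Alignment scoring scheme
#'
#' DNA mode scores +5/-4 (classic nucleotide BLAST rewards) with affine gaps;
#' protein mode uses BLOSUM62 with the stop symbol `*` overridden to mismatch
#' everything.
#'
#' The DNA gap defaults (-16 open, -4 extend) are deliberately strict: with
#' +5/-4 substitution scores, cheaper gaps push local alignment out of the
#' logarithmic (Karlin-Altschul) regime, where the best random alignment
#' score grows linearly with sequence length and no fixed score threshold
#' can separate homology from noise. With these defaults random scores grow
#' logarithmically, so raw-score thresholds behave like they do in BLAST.
#'
#' @param mode `"dna"` or `"protein"`.
#' @param match,mismatch Match/mismatch scores (DNA mode).
#' @param gap_open,gap_extend Gap penalties (non-positive); a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @param matrix Protein substitution matrix name (only `"BLOSUM62"` is
#'   built in).
#' @return A `genefish_scheme` object.
#' @export
scoring_scheme <- function(mode = c("dna", "protein"), match = 5, mismatch = -4,
                           gap_open = if (match.arg(mode) == "dna") -16 else -8,
                           gap_extend = if (match.arg(mode) == "dna") -4 else -2,
                           matrix = "BLOSUM62") {
  mode <- match.arg(mode)
  if (match <= 0 || mismatch >= 0) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  sub <- NULL
  alpha <- ""
  if (mode == "protein") {
    if (!identical(matrix, "BLOSUM62")) stop("unknown substitution matrix: ", matrix)
    sub <- blosum62_star()
    alpha <- paste(rownames(sub), collapse = "")
  }
  structure(list(mode = mode, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix = matrix, submat = sub, alphabet = alpha),
            class = "genefish_scheme")
}

# representation handed to the C++ aligner (positive gap costs)
scheme_c <- function(scheme) {
  list(protein = scheme$mode == "protein", match = scheme$match,
       mismatch = scheme$mismatch, gap_open = -scheme$gap_open,
       gap_extend = -scheme$gap_extend, alphabet = scheme$alphabet,
       submat = scheme$submat)
}

#' Search parameters
#'
#' @param seed_length Exact-word seed length; defaults to 12 for DNA and 4 for
#'   protein queries when left `NULL`.
#' @param min_score Minimum raw alignment score for a hit; defaults to 40
#'   (DNA) or 35 (protein) when left `NULL`.
#' @param top_n_per_shard Hits kept per query per shard after sorting by score
#'   (ties broken by fragment id, so truncation is reproducible).
#' @param fraction Fraction of shards to search, in (0, 1].
#' @return A `genefish_search_params` list.
#' @export
search_params <- function(seed_length = NULL, min_score = NULL,
                          top_n_per_shard = 100, fraction = 1) {
  if (!is.null(seed_length) && seed_length < 3) stop("seed_length must be >= 3")
  if (top_n_per_shard < 1) stop("top_n_per_shard must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  structure(list(seed_length = seed_length, min_score = min_score,
                 top_n_per_shard = as.integer(top_n_per_shard),
                 fraction = fraction),
            class = "genefish_search_params")
}

resolve_search <- function(params, mode) {
  params$seed_length <- as.integer(
    params$seed_length %||% if (mode == "dna") 12L else 4L)
  params$min_score <- as.integer(
    params$min_score %||% if (mode == "dna") 40L else 35L)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Six-frame translation
#'
#' Frames 0-2 translate the forward strand at offsets 0, 1, 2; frames 3-5
#' translate the reverse complement likewise. Standard genetic code, stops as
#' `*`, ambiguous codons as `X`, trailing partial codons dropped.
#'
#' @param dna A single DNA string.
#' @return Character vector of the 6 frame translations (some may be empty
#'   for very short input).
#' @examples
#' translate_six_frames("ATGAAATGA")
#' @export
translate_six_frames <- function(dna) {
  stopifnot(length(dna) == 1L)
  unlist(lapply(cpp_translate6(normalize_dna(dna)), `[[`, 1L))
}

#' Best seeded local alignment of a query against one subject
#'
#' Finds exact shared words of `seed_length` and extends them with exact
#' affine-gap local dynamic programming on a query window around the seed
#' diagonals. The returned score never exceeds the unconstrained local
#' alignment optimum and equals it whenever an exact seed lies inside the
#' optimal alignment. Returns `NULL` when query and subject share no seed or
#' nothing scores above zero.
#'
#' @param query,subject Sequences in the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param seed_length Exact word size nominating candidates.
#' @return A list with `score`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open), or `NULL`.
#' @export
seed_and_extend <- function(query, subject, scheme, seed_length = 12) {
  hits <- cpp_search(query, subject, scheme_c(scheme),
                     as.integer(seed_length), 1L)
  if (nrow(hits) == 0) return(NULL)
  list(score = hits$score[1],
       query_start = hits$q0[1], query_end = hits$q1[1],
       subject_start = hits$s0[1], subject_end = hits$s1[1])
}

# all distinct local alignments (HSPs) of query vs subject above min_score
local_hsps <- function(query, subject, scheme, min_score, max_hsps = 16L) {
  as_tibble(cpp_hsps(query, subject, scheme_c(scheme),
                     as.integer(min_score), as.integer(max_hsps)))
}

# lazily computed six-frame translations of a shard's first-end reads
shard_frames <- function(db, shard_index) {
  key <- sprintf("frames_%d", shard_index)
  if (is.null(db$cache[[key]]))
    db$cache[[key]] <- cpp_translate6(db$shards[[shard_index + 1L]]$seq1)
  db$cache[[key]]
}

#' Search one shard for reads similar to a query
#'
#' DNA queries are searched against each indexed first-end read and its
#' reverse complement (the hit strand is recorded; stored reads are only kept
#' in one orientation). Protein queries are searched against all six
#' translated frames of each read. Hits scoring at least `min_score` are
#' sorted by score (ties by fragment id) and truncated to
#' `top_n_per_shard`.
#'
#' @param query A single query sequence (character) or one-row tibble with
#'   `id`/`seq`.
#' @param db A `genefish_db`.
#' @param shard_index 0-based shard index.
#' @param scheme A [scoring_scheme()]; its mode must match the query alphabet.
#' @param params A [search_params()].
#' @param exclude_ids Fragment ids to drop before top-N truncation (used by
#'   the iteration loop so that each round's retrieval quota goes to reads
#'   not already in the pool).
#' @return Hit tibble: `pair_id`, `shard`, `score`, `query_start`,
#'   `query_end`, `read_start`, `read_end` (forward-read coordinates, 0-based
#'   half-open), `strand`, `frame`.
#' @export
search_shard <- function(query, db, shard_index, scheme, params = search_params(),
                         exclude_ids = NULL) {
  if (is.data.frame(query)) query <- query$seq[1]
  stopifnot(inherits(db, "genefish_db"), inherits(scheme, "genefish_scheme"))
  params <- resolve_search(params, scheme$mode)
  if (scheme$mode == "dna") {
    query <- normalize_dna(query)
    if (guess_alphabet(query) != "dna")
      stop("query contains protein residues but the scheme mode is 'dna'")
  } else {
    query <- toupper(query)
  }
  sh <- db$shards[[shard_index + 1L]]
  sc <- scheme_c(scheme)
  hits <- NULL
  if (scheme$mode == "dna") {
    subjects <- sh$seq1
    qlen <- nchar(query)
    fwd <- cpp_search(query, subjects, sc, params$seed_length, params$min_score)
    rev <- cpp_search(revcomp(query), subjects, sc, params$seed_length, params$min_score)
    fwd <- as_tibble(fwd)
    rev <- as_tibble(rev)
    fwd$strand <- rep("+", nrow(fwd))
    if (nrow(rev)) {
      # hits of the reverse-complemented query: map query spans back
      q0 <- qlen - rev$q1
      rev$q1 <- qlen - rev$q0
      rev$q0 <- q0
    }
    rev$strand <- rep("-", nrow(rev))
    hits <- bind_rows(fwd, rev)
    hits$frame <- 0L
  } else {
    frames <- shard_frames(db, shard_index)
    rl <- nchar(sh$seq1)
    parts <- lapply(0:5, function(f) {
      h <- as_tibble(cpp_search(query, frames[[f + 1L]], sc,
                                params$seed_length, params$min_score))
      if (nrow(h) == 0) return(h)
      h$frame <- f
      off <- f %% 3L
      nt0 <- off + 3L * h$s0
      nt1 <- off + 3L * h$s1
      if (f >= 3L) {           # frame on the reverse complement: mirror
        L <- rl[h$idx]
        tmp <- L - nt1
        nt1 <- L - nt0
        nt0 <- tmp
      }
      h$s0 <- nt0
      h$s1 <- nt1
      h
    })
    hits <- bind_rows(parts)
    hits$strand <- ifelse(hits$frame >= 3L, "-", "+")
  }
  if (nrow(hits) == 0) {
    return(tibble(pair_id = character(), shard = integer(), score = integer(),
                  query_start = integer(), query_end = integer(),
                  read_start = integer(), read_end = integer(),
                  strand = character(), frame = integer()))
  }
  hits$pair_id <- sh$pair_id[hits$idx]
  if (!is.null(exclude_ids)) hits <- hits[!hits$pair_id %in% exclude_ids, ]
  if (nrow(hits) == 0) {
    return(tibble(pair_id = character(), shard = integer(), score = integer(),
                  query_start = integer(), query_end = integer(),
                  read_start = integer(), read_end = integer(),
                  strand = character(), frame = integer()))
  }
  # best hit per fragment; then score-descending, id-ascending truncation
  hits <- hits[order(-hits$score, match(hits$strand, c("+", "-")),
                     hits$frame, method = "radix"), ]
  hits <- hits[!duplicated(hits$pair_id), ]
  hits <- hits[order(-hits$score, hits$pair_id, method = "radix"), ]
  hits <- head(hits, params$top_n_per_shard)
  tibble(pair_id = hits$pair_id, shard = as.integer(shard_index),
         score = hits$score,
         query_start = hits$q0, query_end = hits$q1,
         read_start = hits$s0, read_end = hits$s1,
         strand = hits$strand, frame = as.integer(hits$frame))
}

#' Pool the top hits and their mates across shards
#'
#' Searches every selected shard (see [select_shard_subset()]) with every
#' query, takes the union of the per-query top hits, and fetches the full
#' pairs (hit reads plus mates) from the shards they live in. The pool is
#' deduplicated by fragment id.
#'
#' @param db A `genefish_db`.
#' @param queries Query tibble (`id`, `seq`) or character vector.
#' @param scheme A [scoring_scheme()].
#' @param params A [search_params()]; `params$fraction` selects the shards.
#' @param exclude_ids Fragment ids already retrieved; their hits do not
#'   consume the per-query top-N quota.
#' @return A pair tibble with attribute `n_hits` (total hits across queries
#'   and shards before deduplication).
#' @export
gather_read_pool <- function(db, queries, scheme, params = search_params(),
                             exclude_ids = NULL) {
  if (is.character(queries)) queries <- tibble(id = paste0("q", seq_along(queries)),
                                               seq = queries)
  if (nrow(queries) == 0) stop("queries must be non-empty")
  shard_idx <- select_shard_subset(db, params$fraction)
  pools <- list()
  n_hits <- 0L
  for (s in shard_idx) {
    ids <- character()
    for (qi in seq_len(nrow(queries))) {
      h <- search_shard(queries[qi, ], db, s, scheme, params, exclude_ids)
      n_hits <- n_hits + nrow(h)
      ids <- c(ids, h$pair_id)
    }
    if (length(ids)) pools[[length(pools) + 1L]] <- fetch_mates(db, s, unique(ids))
  }
  pool <- if (length(pools)) distinct(bind_rows(pools), .data$pair_id, .keep_all = TRUE)
          else tibble(pair_id = character(), id1 = character(), seq1 = character(),
                      id2 = character(), seq2 = character())
  attr(pool, "n_hits") <- n_hits
  pool
}
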