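# The sharded read database: pairs are hashed by fragment id into
# approximately equal shards; each shard keeps its first-end reads searchable
# and both mates retrievable. Shards hold random samples of the library, so a
# fraction of them is a valid downsample of the sequencing depth.

#' Shard assignment of fragment ids
#'
#' Deterministic, salted hash placement of read pairs into shards. Both mates
#' of a fragment share the `pair_id` and therefore always land in the same
#' shard. The hash is a salted FNV-1a with an avalanche finalizer, so the
#' assignment is stable across runs, platforms and R sessions (language-level
#' hashing is deliberately not used).
#'
#' @param pair_id Character vector of canonical fragment ids.
#' @param n_shards Number of shards (>= 1).
#' @param salt Salt string recorded in the database manifest.
#' @return Integer vector of 0-based shard indices.
#' @examples
#' shard_of(c("frag1", "frag2"), 4)
#' @export
shard_of <- function(pair_id, n_shards, salt = "v1") {
  stopifnot(is.numeric(n_shards), length(n_shards) == 1L)
  if (n_shards < 1) stop("n_shards must be >= 1")
  cpp_shard_of(as.character(pair_id), as.integer(n_shards), salt)
}

#' Build a sharded read-pair database on disk
#'
#' Distributes read pairs into `n_shards` approximately equal shards keyed by
#' the fragment id and persists them under one directory: a plain-text
#' `manifest.txt` (key=value) plus one TSV per shard holding the fragment id,
#' both read ids and both sequences. Qualities are dropped here; the method is
#' quality-agnostic. Rebuilding from identical pairs and salt produces
#' byte-identical files.
#'
#' @param pairs A pair tibble from [pair_reads()] or
#'   [simulate_paired_reads()].
#' @param path Directory to create (overwritten if it exists).
#' @param n_shards Number of shards; the desk-scale default of 1 is
#'   appropriate below hundreds of MB of reads, while large libraries
#'   parallelize with roughly one shard per 250 MB of input.
#' @param index_kmer Word size recorded for the shard search index (>= 8).
#' @param salt Hash salt; recorded in the manifest.
#' @return A `genefish_db` object (invisibly usable wherever a database is
#'   expected; [load_db()] reopens it from disk).
#' @export
build_db <- function(pairs, path, n_shards = 1, index_kmer = 16, salt = "v1") {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "id1", "seq1", "id2", "seq2") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("no read pairs to build a database from")
  if (n_shards < 1) stop("n_shards must be >= 1")
  if (index_kmer < 8) stop("index_kmer must be >= 8")
  dup <- pairs$pair_id[duplicated(pairs$pair_id)]
  if (length(dup)) stop("duplicate pair_id in input: '", dup[1], "'")
  n_shards <- as.integer(n_shards)
  pairs <- tibble(pair_id = pairs$pair_id,
                  id1 = pairs$id1, seq1 = normalize_dna(pairs$seq1),
                  id2 = pairs$id2, seq2 = normalize_dna(pairs$seq2))
  assign <- shard_of(pairs$pair_id, n_shards, salt)
  fp <- cpp_fingerprint(c(pairs$pair_id, pairs$seq1, pairs$seq2))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  shards <- vector("list", n_shards)
  for (s in seq_len(n_shards) - 1L) {
    sh <- pairs[assign == s, ]
    shards[[s + 1L]] <- sh
    f <- file.path(path, sprintf("shard_%05d.tsv", s))
    write.table(sh, f, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  manifest <- c(format_version = "1",
                n_shards = as.character(n_shards),
                total_pairs = as.character(nrow(pairs)),
                index_kmer = as.character(as.integer(index_kmer)),
                salt = salt,
                source_fingerprint = fp)
  writeLines(paste0(names(manifest), "=", manifest), file.path(path, "manifest.txt"))
  new_genefish_db(path, n_shards, nrow(pairs), as.integer(index_kmer), salt, fp, shards)
}

new_genefish_db <- function(path, n_shards, total_pairs, index_kmer, salt, fp, shards) {
  structure(list(path = path, n_shards = n_shards, total_pairs = total_pairs,
                 index_kmer = index_kmer, salt = salt,
                 source_fingerprint = fp, shards = shards,
                 cache = new.env(parent = emptyenv())),
            class = "genefish_db")
}

#' Open a sharded read database from disk
#'
#' @param path Directory created by [build_db()].
#' @return A `genefish_db` object.
#' @export
load_db <- function(path) {
  mf <- file.path(path, "manifest.txt")
  if (!file.exists(mf)) stop("not a genefish database (no manifest.txt): ", path)
  lines <- readLines(mf)
  man <- setNames(sub("^[^=]*=", "", lines), sub("=.*$", "", lines))
  if (!identical(man[["format_version"]], "1"))
    stop("unsupported database format version: ", man[["format_version"]])
  n_shards <- as.integer(man[["n_shards"]])
  shards <- lapply(seq_len(n_shards) - 1L, function(s) {
    f <- file.path(path, sprintf("shard_%05d.tsv", s))
    if (!file.exists(f)) stop("missing shard file: ", f)
    as_tibble(read.table(f, header = TRUE, sep = "\t", colClasses = "character",
                         quote = ""))
  })
  new_genefish_db(path, n_shards, as.integer(man[["total_pairs"]]),
                  as.integer(man[["index_kmer"]]), man[["salt"]],
                  man[["source_fingerprint"]], shards)
}

#' @export
print.genefish_db <- function(x, ...) {
  cat("<genefish_db> ", x$total_pairs, " read pairs in ", x$n_shards,
      " shard(s)\n", sep = "")
  cat("  path: ", x$path, "\n  salt: ", x$salt,
      "  fingerprint: ", x$source_fingerprint, "\n", sep = "")
  invisible(x)
}

#' Retrieve full read pairs from one shard
#'
#' Returns the complete pair (both mates) for every requested fragment id
#' present in the shard. Ids living in other shards are silently omitted;
#' the caller queries each shard it searched.
#'
#' @param db A `genefish_db`.
#' @param shard_index 0-based shard index.
#' @param pair_ids Character vector (or set) of fragment ids.
#' @return A pair tibble (subset of the shard, in shard order).
#' @export
fetch_mates <- function(db, shard_index, pair_ids) {
  stopifnot(inherits(db, "genefish_db"))
  if (length(shard_index) != 1L || shard_index < 0 || shard_index >= db$n_shards)
    stop("invalid shard index: ", shard_index)
  sh <- db$shards[[shard_index + 1L]]
  sh[sh$pair_id %in% pair_ids, ]
}

#' Choose the shards for a fractional search
#'
#' Because each shard holds a hash-random sample of the library, searching the
#' first `ceil(fraction * n_shards)` shards downsamples the effective coverage
#' without biasing the read sample.
#'
#' @param db A `genefish_db`.
#' @param fraction Fraction of shards to use, in (0, 1].
#' @return Integer vector of 0-based shard indices.
#' @export
select_shard_subset <- function(db, fraction = 1) {
  stopifnot(inherits(db, "genefish_db"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  seq_len(ceiling(fraction * db$n_shards)) - 1L
}
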