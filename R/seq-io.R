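# Reading, writing and pairing of FASTA/FASTQ records. Parsing is delegated to
# Biostrings; a validation layer adds the record-naming errors that the raw
# parser does not provide (notably FASTQ quality-length mismatches).

#' Read sequences from a FASTA or FASTQ file
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a tibble with
#' one row per record. Sequences are uppercased; the record id is the first
#' whitespace-delimited token of the header and the remainder is kept as the
#' description. Qualities are returned as Phred+33 strings for FASTQ input and
#' are `NA` otherwise.
#'
#' @param path Path to the sequence file. `.gz` suffixes are handled
#'   transparently.
#' @param format `"auto"` (detect from the first character, `>` vs `@`),
#'   `"fasta"` or `"fastq"`.
#' @return A tibble with columns `id`, `desc`, `seq`, `qual`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 a read", "ACGT", "acgt"), fa)
#' read_seqs(fa)
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    first <- substr(readLines(con, n = 1L), 1L, 1L)
    close(con)
    if (identical(first, ">")) format <- "fasta"
    else if (identical(first, "@")) format <- "fastq"
    else stop("cannot auto-detect format of ", path,
              ": first character is neither '>' nor '@'")
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("malformed FASTA in ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    headers <- names(set)
    if (is.null(headers)) headers <- rep("", length(set))
    ids <- sub("\\s.*$", "", headers)
    descs <- sub("^\\S*\\s*", "", headers)
    seqs <- toupper(as.character(set))
    quals <- rep(NA_character_, length(set))
    bad <- which(nchar(seqs) == 0L)
    if (length(bad)) {
      i <- bad[1]
      stop("empty sequence for record '", ids[i], "' (record ", i, ") in ", path)
    }
  } else {
    # four-line FASTQ records, validated per record (the fast C parser does
    # not check quality lengths and mis-handles malformed records)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    lines <- readLines(con)
    close(con)
    n <- length(lines)
    if (n == 0) stop("empty FASTQ file: ", path)
    if (n %% 4L != 0L)
      stop("truncated FASTQ in ", path, ": ", n, " lines is not a multiple of 4")
    heads <- lines[seq(1L, n, 4L)]
    seqs <- lines[seq(2L, n, 4L)]
    plus <- lines[seq(3L, n, 4L)]
    quals <- lines[seq(4L, n, 4L)]
    line_of <- function(i) 4L * (i - 1L) + 1L
    bad <- which(!startsWith(heads, "@"))
    if (length(bad))
      stop("malformed FASTQ in ", path, ": line ", line_of(bad[1]),
           " does not start with '@'")
    bad <- which(!startsWith(plus, "+"))
    if (length(bad))
      stop("malformed FASTQ in ", path, ": line ", line_of(bad[1]) + 2L,
           " does not start with '+'")
    headers <- substring(heads, 2L)
    ids <- sub("\\s.*$", "", headers)
    descs <- sub("^\\S*\\s*", "", headers)
    bad <- which(nchar(seqs) == 0L)
    if (length(bad)) {
      i <- bad[1]
      stop("empty sequence for record '", ids[i], "' (record ", i, ", line ",
           line_of(i), ") in ", path)
    }
    bad <- which(nchar(quals) != nchar(seqs))
    if (length(bad)) {
      i <- bad[1]
      stop("FASTQ quality length (", nchar(quals[i]), ") does not match ",
           "sequence length (", nchar(seqs[i]), ") for record '", ids[i],
           "' (record ", i, ", line ", line_of(i), ") in ", path)
    }
    seqs <- toupper(seqs)
  }
  tibble(id = ids, desc = descs, seq = unname(seqs), qual = unname(quals))
}

#' Write sequences to a FASTA file
#'
#' Round-trips through [read_seqs()]: ids and sequences are preserved exactly.
#' Paths ending in `.gz` are written gzip-compressed.
#'
#' @param x A tibble with at least `id` and `seq` columns (a `desc` column, if
#'   present and non-empty, is appended to the header).
#' @param path Output path.
#' @param line_width Bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 70) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  headers <- x$id
  if ("desc" %in% names(x)) {
    has_desc <- !is.na(x$desc) & nzchar(x$desc)
    headers[has_desc] <- paste(x$id[has_desc], x$desc[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(x$seq, headers))
  Biostrings::writeXStringSet(set, path, width = line_width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Canonical fragment id and read end of a read name
#'
#' Strips the common mate suffixes (`/1`, `/2`, `.1`, `.2`, `_1`, `_2`) from a
#' read id, or reads the mate number from a Casava-style comment field
#' (`1:N:0:...`) if one is supplied. Read names without a recognized suffix
#' canonicalize to themselves with an unknown end (`NA`).
#'
#' @param id Character vector of read ids (no whitespace).
#' @param desc Optional character vector of header comments, used for
#'   Casava-style `1:...`/`2:...` mate fields.
#' @return A tibble with columns `pair_id` and `end` (integer 1, 2 or `NA`).
#' @examples
#' canonical_pair_id(c("frag7/1", "frag7/2", "frag7"))
#' @export
canonical_pair_id <- function(id, desc = NULL) {
  stopifnot(is.character(id), all(nzchar(id)))
  m <- regmatches(id, regexec("^(.*)[/._]([12])$", id))
  pair_id <- id
  end <- rep(NA_integer_, length(id))
  hit <- lengths(m) == 3L
  pair_id[hit] <- vapply(m[hit], `[[`, "", 2L)
  end[hit] <- as.integer(vapply(m[hit], `[[`, "", 3L))
  if (!is.null(desc)) {
    cas <- !hit & grepl("^[12][: ]", desc) & nzchar(desc)
    end[cas] <- as.integer(substr(desc[cas], 1L, 1L))
  }
  tibble(pair_id = pair_id, end = end)
}

#' Group reads into mated pairs
#'
#' @param reads1 A read tibble from [read_seqs()]. For `layout = "two_files"`
#'   this is the first-end file; for `"interleaved"` the single interleaved
#'   file; for `"suffixed"` a single file whose read names carry `/1`-style
#'   mate suffixes in any order.
#' @param reads2 The second-end read tibble for `layout = "two_files"`.
#' @param layout Pairing layout.
#' @return A tibble with one row per fragment: `pair_id`, `id1`, `seq1`,
#'   `qual1`, `id2`, `seq2`, `qual2`.
#' @details For `two_files` the pairing is positional; disagreeing mate
#'   suffixes only raise a warning, because many archives carry unsuffixed or
#'   renamed mates. Interleaved and suffixed layouts, where the ids are the
#'   only pairing evidence, fail on a mate-id mismatch.
#' @export
pair_reads <- function(reads1, reads2 = NULL,
                       layout = c("two_files", "interleaved", "suffixed")) {
  layout <- match.arg(layout)
  qual_of <- function(x) if ("qual" %in% names(x)) x$qual else rep(NA_character_, nrow(x))
  if (layout == "two_files") {
    if (is.null(reads2)) stop("layout 'two_files' needs reads2")
    if (nrow(reads1) != nrow(reads2))
      stop("pairing error: files differ in length (", nrow(reads1), " vs ",
           nrow(reads2), " records)")
    c1 <- canonical_pair_id(reads1$id, reads1$desc)
    c2 <- canonical_pair_id(reads2$id, reads2$desc)
    known <- !is.na(c1$end) & !is.na(c2$end)
    bad <- known & (c1$pair_id != c2$pair_id)
    if (any(bad))
      warning("mate ids disagree after canonicalization for ", sum(bad),
              " positional pair(s), e.g. '", reads1$id[which(bad)[1]], "' vs '",
              reads2$id[which(bad)[1]], "'; pairing positionally anyway")
    tibble(pair_id = c1$pair_id,
           id1 = reads1$id, seq1 = reads1$seq, qual1 = qual_of(reads1),
           id2 = reads2$id, seq2 = reads2$seq, qual2 = qual_of(reads2))
  } else if (layout == "interleaved") {
    n <- nrow(reads1)
    if (n %% 2L != 0L)
      stop("pairing error: interleaved file has an odd number of records (", n, ")")
    i1 <- seq(1L, n, by = 2L)
    i2 <- i1 + 1L
    c1 <- canonical_pair_id(reads1$id[i1], reads1$desc[i1])
    c2 <- canonical_pair_id(reads1$id[i2], reads1$desc[i2])
    known <- !is.na(c1$end) & !is.na(c2$end)
    bad <- known & (c1$pair_id != c2$pair_id)
    if (any(bad))
      stop("pairing error: consecutive records '", reads1$id[i1[which(bad)[1]]],
           "' and '", reads1$id[i2[which(bad)[1]]],
           "' canonicalize to different fragments")
    q <- qual_of(reads1)
    tibble(pair_id = c1$pair_id,
           id1 = reads1$id[i1], seq1 = reads1$seq[i1], qual1 = q[i1],
           id2 = reads1$id[i2], seq2 = reads1$seq[i2], qual2 = q[i2])
  } else {
    cc <- canonical_pair_id(reads1$id, reads1$desc)
    if (anyNA(cc$end))
      stop("pairing error: record '", reads1$id[which(is.na(cc$end))[1]],
           "' has no recognizable mate suffix")
    ord <- order(match(cc$pair_id, unique(cc$pair_id)), cc$end)
    ids <- cc$pair_id[ord]
    ends <- cc$end[ord]
    n <- length(ids)
    if (n %% 2L != 0L || !all(ids[seq(1L, n, 2L)] == ids[seq(2L, n, 2L)]) ||
        !all(ends[seq(1L, n, 2L)] == 1L & ends[seq(2L, n, 2L)] == 2L)) {
      counts <- table(cc$pair_id)
      off <- names(counts)[counts != 2L][1]
      if (is.na(off)) off <- ids[1]
      stop("pairing error: fragment '", off, "' does not have exactly one /1 and one /2 read")
    }
    i1 <- ord[seq(1L, n, 2L)]
    i2 <- ord[seq(2L, n, 2L)]
    q <- qual_of(reads1)
    tibble(pair_id = cc$pair_id[i1],
           id1 = reads1$id[i1], seq1 = reads1$seq[i1], qual1 = q[i1],
           id2 = reads1$id[i2], seq2 = reads1$seq[i2], qual2 = q[i2])
  }
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement of DNA strings.
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(seq) cpp_revcomp(toupper(seq))

#' Canonical orientation of a DNA sequence
#'
#' The lexicographically smaller (byte order) of a sequence and its reverse
#' complement; strand-ambiguous sequence sets compare well-defined under it.
#' @param seq Character vector of DNA sequences.
#' @return Character vector of canonical-orientation sequences.
#' @export
canonical_seq <- function(seq) cpp_canonical(toupper(seq))

# uppercase + RNA-to-DNA normalization for sequence entering DNA search/assembly
normalize_dna <- function(seq) chartr("u", "T", chartr("U", "T", toupper(seq)))

#' Guess whether a sequence is DNA or protein
#'
#' A sequence is called protein if it contains residues outside the IUPAC
#' nucleotide alphabet (for example E, F, L, Q or `*`).
#' @param seq Character vector.
#' @return `"dna"` or `"protein"` per element.
#' @export
guess_alphabet <- function(seq) {
  ifelse(grepl("[^ACGTUNRYSWKMBDHV.-]", toupper(seq)), "protein", "dna")
}
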