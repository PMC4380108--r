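# Shared fixture builders and independent oracles. Fixtures are generated in
# code under fixed seeds; nothing is read from disk.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# error-free reads tiling a sequence at a fixed step, with the terminal
# window always covered
tile_reads <- function(seq, read_len = 100, step = 7) {
  L <- nchar(seq)
  starts <- unique(c(seq(1, max(1, L - read_len + 1), by = step), L - read_len + 1))
  substring(seq, starts, starts + read_len - 1)
}

# a pair tibble of n random fragments (both mates random, ids sequential)
random_pairs <- function(n, read_len = 50) {
  tibble::tibble(
    pair_id = sprintf("frag%05d", seq_len(n)),
    id1 = sprintf("frag%05d/1", seq_len(n)),
    seq1 = vapply(seq_len(n), function(i) random_dna(read_len), ""),
    id2 = sprintf("frag%05d/2", seq_len(n)),
    seq2 = vapply(seq_len(n), function(i) random_dna(read_len), ""))
}

# independent optimal local alignment score (Smith-Waterman) via Biostrings
sw_oracle_score <- function(a, b, scheme) {
  if (scheme$mode == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
    s <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = -scheme$gap_open,
      gapExtension = -scheme$gap_extend, scoreOnly = TRUE)
  } else {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = scheme$submat, gapOpening = -scheme$gap_open,
      gapExtension = -scheme$gap_extend, scoreOnly = TRUE)
  }
  as.integer(round(s))
}

# vectorized oracle: optimal local score of one DNA query against many reads,
# best over both read orientations
sw_oracle_scan <- function(query, reads, scheme) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
  score_set <- function(subjects) {
    as.integer(round(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(subjects), Biostrings::DNAString(query),
      type = "local", substitutionMatrix = mat, gapOpening = -scheme$gap_open,
      gapExtension = -scheme$gap_extend, scoreOnly = TRUE)))
  }
  pmax(score_set(reads), score_set(as.character(genefish::revcomp(reads))))
}

# substitute exactly k positions of a DNA string (guaranteed different base)
mutate_fixed <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_tmp_fastq <- function(lines) {
  f <- tempfile(fileext = ".fastq")
  writeLines(lines, f)
  f
}
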