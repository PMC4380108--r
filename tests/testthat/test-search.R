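test_that("six-frame translation follows the standard code and strand symmetry", {
  expect_equal(translate_six_frames("ATGAAATGA")[1], "MK*")
  # frame 3 of the reverse complement of ATGAAATGA reads MK* again
  expect_equal(translate_six_frames("TCATTTCAT")[4], "MK*")
  expect_equal(translate_six_frames("ATGA")[2], "*")   # offset 1: TGA
  expect_equal(translate_six_frames("ATGA")[3], "")    # offset 2: partial codon

  # oracle: Biostrings translation over random sequences, all 6 frames
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna(sample(30:90, 1))
    fr <- translate_six_frames(s)
    d <- Biostrings::DNAString(s)
    rc <- Biostrings::reverseComplement(d)
    for (f in 0:2) {
      for (src in 1:2) {
        x <- if (src == 1) d else rc
        n <- length(x) - f
        n <- n - (n %% 3)
        exp <- if (n < 3) "" else
          as.character(Biostrings::translate(Biostrings::subseq(x, f + 1, f + n),
                                                no.init.codon = TRUE))
        expect_equal(fr[f + 1 + 3 * (src - 1)], exp)
      }
    }
  }
})

test_that("seed_and_extend scores perfect matches exactly", {
  dna <- scoring_scheme("dna")
  set.seed(32)
  flank1 <- random_dna(40)
  q <- "ACGTACGTACGTACGT"
  subj <- paste0(flank1, q, random_dna(44))
  h <- seed_and_extend(q, subj, dna, 12)
  expect_equal(h$score, 16L * 5L)
  expect_equal(c(h$query_start, h$query_end), c(0L, 16L))
  expect_equal(c(h$subject_start, h$subject_end), c(40L, 56L))

  s <- random_dna(60)
  h2 <- seed_and_extend(s, s, dna, 12)
  expect_equal(h2$score, 5L * 60L)
  expect_equal(c(h2$query_start, h2$query_end), c(0L, 60L))

  expect_null(seed_and_extend("ACGTACGTACGTACG", paste(rep("A", 50), collapse = ""),
                              dna, 12))
})

test_that("seeded extension never exceeds the Smith-Waterman optimum and almost always attains it", {
  dna <- scoring_scheme("dna")
  set.seed(33)
  n_hit <- 0L
  n_eq <- 0L
  for (i in 1:200) {
    # half related pairs (common core with mutations), half unrelated
    if (i %% 2 == 0) {
      core <- random_dna(sample(40:100, 1))
      q <- paste0(random_dna(sample(5:30, 1)), core, random_dna(sample(5:30, 1)))
      s <- paste0(random_dna(sample(5:30, 1)), mutate_fixed(core, sample(0:6, 1)),
                  random_dna(sample(5:30, 1)))
    } else {
      q <- random_dna(sample(50:150, 1))
      s <- random_dna(sample(50:150, 1))
    }
    h <- seed_and_extend(q, s, dna, 12)
    if (is.null(h)) next
    n_hit <- n_hit + 1L
    opt <- sw_oracle_score(q, s, dna)
    expect_lte(h$score, opt)
    if (h$score == opt) n_eq <- n_eq + 1L
  }
  expect_gt(n_hit, 50L)
  expect_gte(n_eq / n_hit, 0.95)
})

test_that("protein-mode extension agrees with the BLOSUM62 oracle", {
  prot <- scoring_scheme("protein")
  set.seed(34)
  aa <- setdiff(strsplit(rownames(prot$submat) |> paste(collapse = ""), "")[[1]],
                c("B", "J", "Z", "X", "*"))
  rand_aa <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
  n_eq <- 0L; n_hit <- 0L
  for (i in 1:50) {
    core <- rand_aa(sample(20:40, 1))
    q <- paste0(rand_aa(sample(3:10, 1)), core, rand_aa(sample(3:10, 1)))
    s <- paste0(rand_aa(sample(3:10, 1)), core, rand_aa(sample(3:10, 1)))
    h <- seed_and_extend(q, s, prot, 4)
    if (is.null(h)) next
    n_hit <- n_hit + 1L
    opt <- sw_oracle_score(q, s, prot)
    expect_lte(h$score, opt)
    if (h$score == opt) n_eq <- n_eq + 1L
  }
  expect_gt(n_hit, 40L)
  expect_gte(n_eq / n_hit, 0.95)
})

make_planted_db <- function(genome_reads, n_random, read_len = 100, seed = 1,
                            n_shards = 1) {
  set.seed(seed)
  rnd <- vapply(seq_len(n_random), function(i) random_dna(read_len), "")
  seq1 <- c(genome_reads, rnd)
  n <- length(seq1)
  pairs <- tibble::tibble(pair_id = sprintf("p%04d", seq_len(n)),
                          id1 = sprintf("p%04d/1", seq_len(n)), seq1 = seq1,
                          id2 = sprintf("p%04d/2", seq_len(n)),
                          seq2 = vapply(seq_len(n), function(i) random_dna(read_len), ""))
  build_db(pairs, tempfile("plantdb"), n_shards = n_shards)
}

test_that("search_shard finds planted reads on the correct strand", {
  set.seed(35)
  gene <- random_dna(400)
  query <- substr(gene, 101, 300)
  fwd_read <- substr(gene, 151, 250)
  rev_read <- revcomp(substr(gene, 161, 260))
  db <- make_planted_db(c(fwd_read, rev_read), 98, seed = 1035)
  hits <- search_shard(query, db, 0, scoring_scheme("dna"))
  expect_equal(sort(hits$pair_id), c("p0001", "p0002"))
  expect_equal(hits$strand[hits$pair_id == "p0001"], "+")
  expect_equal(hits$strand[hits$pair_id == "p0002"], "-")
  expect_equal(hits$score, c(500L, 500L))
  # read spans are reported in stored-read forward coordinates
  expect_equal(hits$read_start, c(0L, 0L))
  expect_equal(hits$read_end, c(100L, 100L))
})

test_that("search_shard equals an exhaustive Smith-Waterman scan on planted shards", {
  dna <- scoring_scheme("dna")
  set.seed(36)
  for (trial in 1:8) {
    gene <- random_dna(300)
    query <- substr(gene, 51, 250)
    planted_pos <- sample(51:151, 10)
    planted <- vapply(planted_pos, function(p) {
      r <- substr(gene, p, p + 99)
      r <- mutate_fixed(r, sample(0:3, 1))
      if (runif(1) < 0.5) revcomp(r) else r
    }, "")
    db <- make_planted_db(planted, 290, seed = 2000 + trial)
    params <- search_params(min_score = 300, top_n_per_shard = 1000)
    hits <- search_shard(query, db, 0, dna, params)
    # oracle: full scan of every read in both orientations
    sh <- db$shards[[1]]
    oracle_scores <- sw_oracle_scan(query, sh$seq1, dna)
    oracle_ids <- sh$pair_id[oracle_scores >= 300]
    expect_setequal(hits$pair_id, oracle_ids)
    # all ten planted reads overlap the query enough to be found
    expect_true(all(sprintf("p%04d", 1:10) %in% hits$pair_id))
    # scores agree with the oracle
    expect_equal(hits$score[match(oracle_ids, hits$pair_id)],
                 oracle_scores[match(oracle_ids, sh$pair_id)])
  }
})

test_that("reverse-complementing the query swaps strands and keeps scores", {
  set.seed(37)
  gene <- random_dna(500)
  planted <- vapply(sample(1:400, 8), function(p) substr(gene, p, p + 99), "")
  db <- make_planted_db(planted, 192, seed = 1037)
  q <- substr(gene, 101, 350)
  h1 <- search_shard(q, db, 0, scoring_scheme("dna"))
  h2 <- search_shard(revcomp(q), db, 0, scoring_scheme("dna"))
  expect_setequal(h1$pair_id, h2$pair_id)
  m <- match(h1$pair_id, h2$pair_id)
  expect_equal(h1$score, h2$score[m])
  expect_true(all(h1$strand != h2$strand[m]))
})

test_that("raising min_score or lowering top_n only shrinks the hit set", {
  set.seed(38)
  gene <- random_dna(600)
  planted <- vapply(sample(1:500, 30), function(p) {
    mutate_fixed(substr(gene, p, p + 99), sample(0:10, 1))
  }, "")
  db <- make_planted_db(planted, 170, seed = 1038)
  q <- gene
  base <- search_shard(q, db, 0, scoring_scheme("dna"),
                       search_params(min_score = 40, top_n_per_shard = 1000))
  strict <- search_shard(q, db, 0, scoring_scheme("dna"),
                         search_params(min_score = 120, top_n_per_shard = 1000))
  expect_true(all(strict$pair_id %in% base$pair_id))
  top5 <- search_shard(q, db, 0, scoring_scheme("dna"),
                       search_params(min_score = 40, top_n_per_shard = 5))
  expect_equal(nrow(top5), 5L)
  expect_true(all(top5$pair_id %in% base$pair_id))
  expect_equal(top5$score, head(base$score, 5))
})

test_that("protein queries find reads through all six frames", {
  set.seed(39)
  cds <- paste(sample(setdiff(as.vector(outer(outer(c("T","C","A","G"), c("T","C","A","G"),
                       paste0), c("T","C","A","G"), paste0)), c("TAA","TAG","TGA")),
                      120, replace = TRUE), collapse = "")
  protein <- translate_six_frames(cds)[1]
  reads <- c(substr(cds, 10, 109),            # frame of the read varies with offset
             substr(cds, 11, 110),
             revcomp(substr(cds, 50, 149)))
  db <- make_planted_db(reads, 197, seed = 1039)
  hits <- search_shard(protein, db, 0, scoring_scheme("protein"))
  expect_true(all(c("p0001", "p0002", "p0003") %in% hits$pair_id))
  expect_true(all(hits$frame[match(c("p0001", "p0002"), hits$pair_id)] < 3))
  expect_gte(hits$frame[hits$pair_id == "p0003"], 3)
  expect_error(search_shard(protein, db, 0, scoring_scheme("dna")), "protein residues")
})

test_that("gather_read_pool unions hits with mates, deduplicated", {
  set.seed(40)
  gene <- random_dna(400)
  planted <- vapply(c(1, 50, 100, 150, 200), function(p) substr(gene, p, p + 99), "")
  db <- make_planted_db(planted, 95, seed = 1040)
  q1 <- substr(gene, 1, 200)
  q2 <- substr(gene, 100, 300)   # overlapping hit sets
  pool <- gather_read_pool(db, c(q1, q2), scoring_scheme("dna"),
                           search_params(min_score = 100))
  expect_equal(anyDuplicated(pool$pair_id), 0L)
  expect_true(all(sprintf("p%04d", 1:5) %in% pool$pair_id))
  expect_true(all(c("seq1", "seq2") %in% names(pool)))
  expect_gt(attr(pool, "n_hits"), nrow(pool) - 1)
})

test_that("a fraction of shards searches only the leading shards", {
  set.seed(41)
  gene <- random_dna(300)
  planted <- vapply(1:6, function(p) substr(gene, p * 30, p * 30 + 99), "")
  db <- make_planted_db(planted, 394, seed = 1041, n_shards = 2)
  full <- gather_read_pool(db, gene, scoring_scheme("dna"),
                           search_params(min_score = 100, fraction = 1))
  half <- gather_read_pool(db, gene, scoring_scheme("dna"),
                           search_params(min_score = 100, fraction = 0.5))
  in_shard0 <- db$shards[[1]]$pair_id
  expect_true(all(half$pair_id %in% in_shard0))
  expect_true(all(half$pair_id %in% full$pair_id))
})
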