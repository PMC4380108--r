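# small end-to-end fixture shared within this file
make_fixture <- function(seed = 61, genome_len = 20000, n_genes = 2,
                         coverage = 30, error_rate = 0) {
  g <- simulate_genome(genome_len, n_genes, seed = seed)
  pairs <- simulate_paired_reads(g, coverage = coverage, error_rate = error_rate,
                                 seed = seed + 1)
  db <- build_db(pairs, tempfile("fixdb"))
  list(genome = g, db = db)
}

test_that("contig filtering keeps the highest scorers against the target", {
  set.seed(62)
  target <- random_dna(300)
  related <- vapply(1:7, function(i) {
    paste0(random_dna(50), mutate_fixed(target, 5), random_dna(50))
  }, "")
  unrelated <- vapply(1:3, function(i) random_dna(400), "")
  contigs <- tibble::tibble(contig_id = paste0("c", 1:10),
                            seq = c(related, unrelated),
                            length = nchar(c(related, unrelated)),
                            mean_kmer_coverage = 1)
  params <- genefish_params(keep_top_contigs = 5)
  kept <- score_contigs_vs_target(contigs, target, scoring_scheme("dna"), params)
  expect_equal(nrow(kept), 5L)
  expect_true(all(kept$contig_id %in% paste0("c", 1:7)))
  expect_equal(kept$score, sort(kept$score, decreasing = TRUE))

  # a contig containing the target verbatim scores 5 * |target|
  verb <- tibble::tibble(contig_id = "v", seq = paste0("AAAA", target, "GGGG"),
                         length = 308L, mean_kmer_coverage = 1)
  kv <- score_contigs_vs_target(verb, target, scoring_scheme("dna"), params)
  expect_equal(kv$score, 5L * 300L)

  # random contigs fall below the threshold and are dropped
  rand <- tibble::tibble(contig_id = "r", seq = random_dna(150), length = 150L,
                         mean_kmer_coverage = 1)
  expect_equal(nrow(score_contigs_vs_target(rand, target, scoring_scheme("dna"),
                                            params)), 0L)
})

test_that("autocomplete requires the alignment to reach both query ends", {
  set.seed(63)
  target <- random_dna(1000)
  params <- genefish_params()
  dna <- scoring_scheme("dna")
  full <- paste0(random_dna(200), target, random_dna(200))
  expect_true(check_autocomplete(full, target, dna, params))
  middle <- substr(target, 201, 800)
  expect_false(check_autocomplete(middle, target, dna, params))
  start_only <- substr(target, 1, 600)
  expect_false(check_autocomplete(start_only, target, dna, params))
  # ends in different "exons" of the contig still autocomplete via the union
  split_contig <- paste0(substr(target, 1, 500), random_dna(300),
                         substr(target, 501, 1000))
  expect_true(check_autocomplete(split_contig, target, dna, params))
})

test_that("convergence compares canonical sequence multisets only", {
  a <- tibble::tibble(contig_id = c("x", "y"), seq = c("ACGTACGTACGTA", "TTTTACGTACGT"))
  b <- tibble::tibble(contig_id = c("p", "q"),
                      seq = rev(c(revcomp("ACGTACGTACGTA"), "TTTTACGTACGT")))
  expect_true(converged(a, b))
  c2 <- a
  c2$seq[1] <- paste0(c2$seq[1], "A")
  expect_false(converged(c2, a))
  empty <- a[0, ]
  expect_true(converged(empty, empty))
})

test_that("run_genefish assembles a gene to autocomplete on clean data", {
  fx <- make_fixture(seed = 61)
  g <- fx$genome
  cds <- gene_cds(g, "gene01")
  params <- genefish_params(autocomplete = TRUE,
                         assembly = assembly_params(min_kmer_count = 2))
  res <- run_genefish(fx$db, tibble::tibble(id = "gene01", seq = cds), params)
  expect_s3_class(res, "genefish_result")
  expect_true(res$termination %in% c("autocomplete", "converged"))
  expect_lte(length(res$trace), 5L)
  expect_equal(res$termination, res$trace[[length(res$trace)]]$status)
  # the locus is recovered completely and exactly
  expect_gte(percent_coverage(res$best_contig, gene_locus(g, "gene01")), 0.99)
  st <- contig_stats(tibble::tibble(contig_id = "c", seq = res$best_contig$seq,
                                    reference_id = "gene01"),
                     tibble::tibble(id = "gene01", seq = cds))
  expect_equal(st$p_distance, 0)
  # trace tidies into one row per iteration
  tr <- tidy(res)
  expect_equal(tr$iteration, seq_len(nrow(tr)) - 1L)
  expect_equal(glance(res)$termination, res$termination)
})

test_that("a target absent from the genome returns no_hits at iteration 0", {
  fx <- make_fixture(seed = 64, genome_len = 12000, n_genes = 1)
  set.seed(65)
  absent <- random_dna(600)
  res <- run_genefish(fx$db, tibble::tibble(id = "missing", seq = absent),
                   genefish_params())
  expect_equal(res$termination, "no_hits")
  expect_length(res$trace, 1L)
  expect_equal(nrow(res$final_contigs), 0L)
  expect_null(res$best_contig)
})

test_that("a saturated pool converges by iteration 1", {
  # single short contig assembled from an isolated island of reads: iteration 1
  # retrieves the same pool, reassembles identical contigs, and converges
  set.seed(66)
  island <- random_dna(600)
  reads1 <- tile_reads(island, 100, 10)
  n <- length(reads1)
  pairs <- tibble::tibble(pair_id = sprintf("i%03d", seq_len(n)),
                          id1 = sprintf("i%03d/1", seq_len(n)), seq1 = reads1,
                          id2 = sprintf("i%03d/2", seq_len(n)),
                          seq2 = rev(revcomp(reads1)))
  db <- build_db(pairs, tempfile("islanddb"))
  params <- genefish_params(assembly = assembly_params(min_kmer_count = 1))
  res <- run_genefish(db, c(island = island), params)
  expect_equal(res$termination, "converged")
  expect_equal(length(res$trace), 2L)
})

test_that("target coverage grows monotonically across iterations on clean data", {
  fx <- make_fixture(seed = 67, genome_len = 25000, n_genes = 2)
  g <- fx$genome
  cds <- gene_cds(g, "gene02")
  params <- genefish_params(max_iterations = 4,
                         search = search_params(top_n_per_shard = 30),
                         assembly = assembly_params(min_kmer_count = 2))
  res <- run_genefish(fx$db, tibble::tibble(id = "gene02", seq = cds), params)
  covs <- vapply(res$trace, function(r) {
    if (nrow(r$kept_contigs) == 0) return(0)
    max(vapply(r$kept_contigs$seq, percent_coverage, 0, reference = cds))
  }, 0)
  expect_true(all(diff(covs) >= -1e-9))
})

test_that("protein targets drive a translated search at iteration 0", {
  fx <- make_fixture(seed = 68, genome_len = 15000, n_genes = 1)
  g <- fx$genome
  prot <- gene_protein(g, "gene01")
  params <- genefish_params(autocomplete = TRUE,
                         assembly = assembly_params(min_kmer_count = 2))
  res <- run_genefish(fx$db, tibble::tibble(id = "gene01p", seq = prot), params)
  expect_true(res$termination %in% c("autocomplete", "converged", "max_iterations"))
  expect_gte(percent_coverage(res$best_contig, gene_locus(g, "gene01")), 0.95)
})

test_that("identical inputs reproduce byte-identical results", {
  fx <- make_fixture(seed = 69, genome_len = 12000, n_genes = 1)
  cds <- gene_cds(fx$genome, "gene01")
  params <- genefish_params(autocomplete = TRUE,
                         assembly = assembly_params(min_kmer_count = 2))
  r1 <- run_genefish(fx$db, tibble::tibble(id = "g", seq = cds), params)
  r2 <- run_genefish(fx$db, tibble::tibble(id = "g", seq = cds), params)
  expect_equal(r1$final_contigs, r2$final_contigs)
  expect_equal(tidy(r1), tidy(r2))
})
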