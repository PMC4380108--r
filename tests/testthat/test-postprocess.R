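test_that("overlap alignment handles identity, containment and divergence", {
  dna <- metric_scheme()
  al <- semi_global_align("ACGT", "ACGT", dna)
  expect_equal(al$a, "ACGT")
  expect_equal(al$b, "ACGT")
  expect_equal(al$comparable_sites, 4L)
  expect_equal(al$differing_sites, 0L)

  al2 <- semi_global_align("ACGT", "CG", dna)
  expect_equal(al2$comparable_sites, 2L)
  expect_equal(al2$differing_sites, 0L)
  expect_equal(al2$score, 10L)  # the CG core, end gaps free
  expect_equal(p_distance(al2), 0)

  # optimal score matches a full DP oracle on diverged pairs
  set.seed(71)
  for (i in 1:10) {
    src <- random_dna(300)
    qry <- mutate_fixed(src, 30)
    al3 <- semi_global_align(src, qry, dna)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qry), Biostrings::DNAString(src), type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(5, -4, baseOnly = TRUE),
      gapOpening = -dna$gap_open, gapExtension = -dna$gap_extend, scoreOnly = TRUE)
    expect_equal(al3$score, as.integer(round(oracle)))
  }
  expect_error(semi_global_align("", "ACGT", dna), "empty")
})

test_that("p_distance counts differing comparable sites and excludes gaps and Ns", {
  expect_equal(p_distance(c("ACGT", "ACGT")), 0)
  expect_equal(p_distance(c("ACGT", "ACGA")), 0.25)
  expect_equal(p_distance(c("AC-GT", "ACTGA")), 0.25)  # gap column excluded
  expect_equal(p_distance(c("ACNT", "ACGT")), 0)       # N column excluded
  expect_true(is.na(p_distance(c("----", "ACGT"))))
  # symmetry and bounds on random gapped pairs
  set.seed(72)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 50, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 50, replace = TRUE), collapse = "")
    d1 <- p_distance(c(a, b))
    expect_equal(d1, p_distance(c(b, a)))
    if (!is.na(d1)) expect_true(d1 >= 0 && d1 <= 1)
  }
})

test_that("p_distance recovers simulated divergence within binomial bounds", {
  set.seed(73)
  for (d in c(0.05, 0.1, 0.2)) {
    src <- random_dna(2000)
    hom <- withr::with_seed(74, as.character(genefish:::cpp_mutate(src, d)))
    al <- semi_global_align(src, hom)
    n <- al$comparable_sites
    expect_lte(abs(p_distance(al) - d), 3 * sqrt(d * (1 - d) / n))
  }
})

test_that("percent_coverage measures reference positions in either orientation", {
  set.seed(75)
  ref <- random_dna(600)
  expect_equal(percent_coverage(ref, ref), 1)
  expect_equal(percent_coverage(substr(ref, 1, 300), ref), 0.5)
  expect_equal(percent_coverage(revcomp(ref), ref), 1)
  contig <- paste0(random_dna(100), ref, random_dna(100))
  expect_equal(percent_coverage(contig, ref), 1)
  expect_equal(percent_coverage(contig, ref), percent_coverage(revcomp(contig), ref))
})

# a small simulated proteome fixture: DNA coding sequences + their proteins
make_proteome <- function(n_genes, n_codons = 120, seed = 1) {
  g <- simulate_genome(3000 + 2200 * n_genes, n_genes, exons_per_gene = 1,
                       seed = seed, exon_bp = c(3 * n_codons, 3 * n_codons))
  ids <- g$genes$gene_id
  list(genome = g,
       cds = setNames(vapply(ids, gene_cds, "", genome = g), ids),
       prot = tibble::tibble(id = ids,
                             seq = vapply(ids, gene_protein, "", genome = g)))
}

test_that("each gene's own coding sequence is its reciprocal best hit", {
  px <- make_proteome(12, seed = 76)
  for (id in px$prot$id) {
    call <- reciprocal_best_hit(px$cds[[id]], id, px$prot)
    expect_true(call$is_ortholog)
    expect_equal(call$best_reference_hit, id)
  }
})

test_that("a paralog closer to another family member fails the reciprocal test", {
  set.seed(77)
  ancestor <- paste(sample(setdiff(as.vector(outer(outer(c("T","C","A","G"),
    c("T","C","A","G"), paste0), c("T","C","A","G"), paste0)),
    c("TAA","TAG","TGA")), 150, replace = TRUE), collapse = "")
  gene_g <- withr::with_seed(78, as.character(genefish:::cpp_mutate(ancestor, 0.10)))
  gene_h <- withr::with_seed(79, as.character(genefish:::cpp_mutate(ancestor, 0.02)))
  contig <- withr::with_seed(80, as.character(genefish:::cpp_mutate(gene_h, 0.005)))
  prot <- function(x) sub("\\*$", "", translate_six_frames(x)[1])
  proteome <- tibble::tibble(id = c("g", "h"), seq = c(prot(gene_g), prot(gene_h)))
  call <- reciprocal_best_hit(contig, "g", proteome)
  expect_false(call$is_ortholog)
  expect_equal(call$best_reference_hit, "h")
  expect_error(reciprocal_best_hit(contig, "zz", proteome), "absent")
})

test_that("contig_stats assembles the metric table", {
  px <- make_proteome(3, seed = 81)
  refs <- tibble::tibble(id = names(px$cds), seq = unname(px$cds))
  contigs <- tibble::tibble(contig_id = paste0("k", 1:2),
                            seq = c(px$cds[[1]], revcomp(px$cds[[2]])),
                            reference_id = refs$id[1:2])
  st <- contig_stats(contigs, refs, proteome = px$prot)
  expect_equal(nrow(st), 2L)
  expect_equal(st$percent_coverage, c(1, 1))
  expect_equal(st$p_distance, c(0, 0))
  expect_true(all(st$is_ortholog))
})
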