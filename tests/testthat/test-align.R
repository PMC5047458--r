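test_that("anchored mode reproduces the full-DP optimum on small instances", {
  set.seed(101)
  for (i in 1:25) {
    toy <- mk_toy_gene(n_ex = sample(2:4, 1), ex_len = sample(20:40, 1),
                       in_len = sample(45:120, 1))
    mf <- spliced_align(toy$genomic, toy$cdna, align_params(mode = "full_dp"))
    ma <- spliced_align(toy$genomic, toy$cdna, align_params(mode = "anchored"))
    expect_equal(ma$score, mf$score)
    expect_identical(ma$exons, mf$exons)
    expect_identical(ma$introns, mf$introns)
  }
})

test_that("a 60-nt toy gene with one 45-nt intron is recovered identically in both modes", {
  set.seed(77)
  ex1 <- random_dna(30); ex2 <- random_dna(30)
  intron <- paste0("GT", random_dna(41), "AG")
  genomic <- paste0(random_dna(20), ex1, intron, ex2, random_dna(20))
  cdna <- paste0(ex1, ex2)
  mf <- spliced_align(genomic, cdna, align_params(mode = "full_dp"))
  ma <- spliced_align(genomic, cdna, align_params(mode = "anchored"))
  expect_identical(mf$exons, ma$exons)
  expect_equal(nrow(mf$introns), 1)
  expect_equal(mf$introns$end - mf$introns$start + 1L, 45L)
})

test_that("intron-free genomic equal to cDNA gives one spanning exon", {
  s <- with_seed(5, random_dna(400))
  m <- spliced_align(s, s, align_params(mode = "full_dp"))
  expect_equal(nrow(m$exons), 1)
  expect_equal(m$exons$start, 1L)
  expect_equal(m$exons$end, 400L)
  expect_equal(nrow(m$introns), 0)
  expect_equal(m$mismatch_count, 0L)
})

test_that("no gene found returns an empty model, not an error", {
  decoy <- with_seed(8, random_dna(5000))
  cdna <- generate_cdna(exon_sizes_for(), seed = 1063)$cdna
  m <- spliced_align(decoy, cdna)
  expect_true(is_empty_model(m))
  expect_equal(length(annotate_contig(decoy, cdna)), 0)
})

test_that("mutation-free synthetic genes are recovered with the printed structure", {
  for (gene in c("PLE-1", "PLE-G2")) {
    spec <- cluster_spec(gene_order = gene, seed = 1063)
    g <- generate_gene(spec, gene)
    m <- spliced_align(g$seq, g$cdna)
    ex <- dplyr::arrange(m$exons, exon)
    expect_equal(as.integer(ex$end - ex$start + 1L), exon_sizes_for())
    tr <- dplyr::arrange(g$truth$exons, exon)
    expect_identical(ex$start, tr$start)
    expect_identical(ex$end, tr$end)
    it <- dplyr::arrange(m$introns, intron)
    expect_equal(as.integer(it$end - it$start + 1L), intron_sizes_for(gene))
    # the spliced CDS is the planted per-isoform CDS; it differs from the
    # reference cDNA only at the recoded diagnostic codons
    expect_identical(m$cds_sequence, g$truth$cds[[gene]])
    expected_mm <- sum(strsplit(g$truth$cds[[gene]], "")[[1]] !=
                         strsplit(g$cdna, "")[[1]])
    expect_equal(m$mismatch_count, expected_mm)
    if (gene == "PLE-1") expect_equal(m$mismatch_count, 0L)
  }
})

test_that("joined exon sequence differs from the cDNA by exactly mismatch_count substitutions", {
  spec <- cluster_spec(gene_order = "PLE-1", point_mutation_rate = 0.003,
                       seed = 23)
  g <- generate_gene(spec, "PLE-1")
  m <- spliced_align(g$seq, g$cdna)
  expect_equal(nchar(m$cds_sequence), nchar(g$cdna))
  subs <- sum(strsplit(m$cds_sequence, "")[[1]] != strsplit(g$cdna, "")[[1]])
  expect_equal(subs, m$mismatch_count)
})

test_that("annotating the reverse complement mirrors coordinates and flips strand", {
  spec <- cluster_spec(gene_order = "PLE-G2", seed = 6)
  g <- generate_gene(spec, "PLE-G2")
  m_fwd <- spliced_align(g$seq, g$cdna)
  m_rev <- spliced_align(revcomp(g$seq), g$cdna)
  n <- nchar(g$seq)
  expect_equal(m_fwd$strand, "+")
  expect_equal(m_rev$strand, "-")
  expect_equal(m_rev$score, m_fwd$score)
  mirrored <- dplyr::arrange(
    tibble::tibble(start = n - m_rev$exons$end + 1L,
                   end = n - m_rev$exons$start + 1L), start)
  expect_identical(mirrored$start, dplyr::arrange(m_fwd$exons, start)$start)
  expect_identical(mirrored$end, dplyr::arrange(m_fwd$exons, start)$end)
  expect_identical(m_rev$cds_sequence, m_fwd$cds_sequence)
})

test_that("annotate_contig finds each gene of a cluster once, with truth coordinates", {
  spec <- cluster_spec(gene_order = c("PLE-G2", "PLE-1"), intergenic_len = 8000L,
                       seed = 1063)
  sim <- generate_cluster(spec)
  models <- annotate_contig(sim$seq, sim$cdna)
  expect_equal(length(models), 2)
  tr_bodies <- sim$truth$genes
  for (k in 1:2) {
    ex <- models[[k]]$exons
    expect_equal(min(ex$start), tr_bodies$body_start[k])
    expect_equal(max(ex$end), tr_bodies$body_end[k])
  }
})

test_that("minus-strand gene copies are reported with the truth strand", {
  spec <- cluster_spec(gene_order = c("PLE-G2", "PLE-1"), intergenic_len = 8000L,
                       gene_strands = c("PLE-G2" = "+", "PLE-1" = "-"),
                       seed = 31)
  sim <- generate_cluster(spec)
  models <- annotate_contig(sim$seq, sim$cdna)
  expect_equal(length(models), 2)
  expect_equal(vapply(models, function(m) m$strand, character(1)),
               c("+", "-"))
  m2 <- models[[2]]
  tr <- dplyr::arrange(dplyr::filter(sim$truth$exons, gene_id == "PLE-1"), start)
  expect_identical(dplyr::arrange(m2$exons, start)$start, tr$start)
  expect_identical(dplyr::arrange(m2$exons, start)$end, tr$end)
})

test_that("extract_regions returns the 6-kb upstream record ending at -1", {
  spec <- cluster_spec(gene_order = "PLE-G2", seed = 1063)
  g <- generate_gene(spec, "PLE-G2")
  m <- spliced_align(g$seq, g$cdna)
  reg <- extract_regions(m, g$seq, upstream_len = 6000)
  up <- reg[reg$region == "upstream", ]
  expect_equal(nchar(up$sequence), 6000)
  expect_false(up$truncated)
  expect_equal(up$promoter_start, -6000L)
  expect_equal(up$promoter_end, -1L)
  expect_identical(up$sequence, substr(g$seq, 1, 6000))
  i2 <- reg[reg$region == "intron2", ]
  expect_equal(nchar(i2$sequence), 2195)
  cds <- reg[reg$region == "cds", ]
  expect_identical(cds$sequence, m$cds_sequence)
})

test_that("upstream region truncates and flags at the contig boundary", {
  set.seed(15)
  toy <- mk_toy_gene(n_ex = 2, ex_len = 30, in_len = 60, flank = 40)
  m <- spliced_align(toy$genomic, toy$cdna, align_params(mode = "full_dp"))
  reg <- extract_regions(m, toy$genomic, upstream_len = 500)
  up <- reg[reg$region == "upstream", ]
  expect_true(up$truncated)
  expect_equal(nchar(up$sequence), 40)
})

test_that("pairwise identity counts matches over alignment columns", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT")$identity, 100)
  expect_equal(pairwise_identity("ACGT", "ACGA")$identity, 75)
  r <- pairwise_identity("MKLVVF", "MKLVVF", alphabet = "aa")
  expect_equal(r$identity, 100)
  expect_equal(r$gaps, 0)
  # a deletion shows up as gap columns
  r2 <- pairwise_identity("ACGTACGTACGT", "ACGTACGT")
  expect_gt(r2$gaps, 0)
})

test_that("model_summary reports the printed-table layout", {
  spec <- cluster_spec(gene_order = "PLE-1", seed = 1063)
  g <- generate_gene(spec, "PLE-1")
  m <- spliced_align(g$seq, g$cdna)
  s <- model_summary(list(m))
  expect_equal(s$exon8, 39)
  expect_equal(s$intron2, 5403)
  expect_equal(s$span, 1698 + 32069)
})
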