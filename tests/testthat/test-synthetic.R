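test_that("generate_cdna builds a clean CDS partitioned into the given exons", {
  rec <- generate_cdna(exon_sizes_for("gamma-PLE"), seed = 1063)
  expect_equal(nchar(rec$cdna), 1698)
  expect_equal(substr(rec$cdna, 1, 3), "ATG")
  aa <- rec$protein
  expect_false(grepl("*", aa, fixed = TRUE))
  expect_equal(nchar(aa), 565)
  expect_equal(nrow(rec$boundaries), 14)
  expect_equal(rec$boundaries$end[14], 1698)
  expect_equal(rec$boundaries$end - rec$boundaries$start + 1L,
               exon_sizes_for("gamma-PLE"))
})

test_that("minimal two-exon CDS and spec validation", {
  rec <- generate_cdna(c(3, 3), seed = 1)
  expect_equal(nchar(rec$cdna), 6)
  expect_equal(substr(rec$cdna, 1, 3), "ATG")
  expect_equal(nrow(rec$boundaries), 2)
  expect_error(generate_cdna(c(4, 3)), "multiple of 3")
})

test_that("identical seed gives byte-identical output, different seed differs", {
  a <- generate_cdna(exon_sizes_for(), seed = 7)$cdna
  b <- generate_cdna(exon_sizes_for(), seed = 7)$cdna
  d <- generate_cdna(exon_sizes_for(), seed = 8)$cdna
  expect_identical(a, b)
  expect_false(identical(a, d))

  s1 <- generate_gene(cluster_spec(gene_order = "PLE-1", seed = 5), "PLE-1")
  s2 <- generate_gene(cluster_spec(gene_order = "PLE-1", seed = 5), "PLE-1")
  expect_identical(s1$seq, s2$seq)
})

test_that("generated gene has printed body length and GT-AG introns", {
  spec <- cluster_spec(gene_order = "PLE-1", seed = 1063)
  g <- generate_gene(spec, "PLE-1")
  expect_equal(nchar(g$seq), 6000 + 1698 + 32069 + 200)
  tr <- g$truth
  expect_equal(tr$genes$body_end - tr$genes$body_start + 1L, 1698 + 32069)
  intr <- dplyr::arrange(tr$introns, intron)
  expect_equal(intr$end - intr$start + 1L, intron_sizes_for("PLE-1"))
  expect_true(all(substring(g$seq, intr$start, intr$start + 1) == "GT"))
  expect_true(all(substring(g$seq, intr$end - 1, intr$end) == "AG"))
})

test_that("GT-AG and no-internal-stop invariants hold across seeds", {
  for (sd in c(2, 11, 29)) {
    spec <- cluster_spec(gene_order = "PLE-G2", seed = sd)
    g <- generate_gene(spec, "PLE-G2")
    intr <- g$truth$introns
    expect_true(all(substring(g$seq, intr$start, intr$start + 1) == "GT"))
    expect_true(all(substring(g$seq, intr$end - 1, intr$end) == "AG"))
    ex <- dplyr::arrange(g$truth$exons, exon)
    cds <- paste(substring(g$seq, ex$start, ex$end), collapse = "")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("planted repeat copies are exact reverse complements at spec'd coordinates", {
  spec <- cluster_spec(gene_order = "PLE-1", seed = 1063)
  g <- generate_gene(spec, "PLE-1")
  rp <- g$truth$repeats
  c1 <- substr(g$seq, rp$copy1_start, rp$copy1_end)
  c2 <- substr(g$seq, rp$copy2_start, rp$copy2_end)
  expect_equal(nchar(c1), 720)
  expect_identical(c1, revcomp(c2))
  # promoter coordinates: -5132..-4413 and -802..-83
  expect_equal(rp$copy1_start - 6000L - 1L, -5132L)
  expect_equal(rp$copy1_end - 6000L - 1L, -4413L)
  expect_equal(rp$copy2_start - 6000L - 1L, -802L)
  expect_equal(rp$copy2_end - 6000L - 1L, -83L)
})

test_that("repeat plant with a mismatch budget stays within it", {
  spec <- cluster_spec(gene_order = "PLE-1",
                       repeat_plant = repeat_plant_spec(max_mismatches = 3),
                       seed = 4)
  g <- generate_gene(spec, "PLE-1")
  rp <- g$truth$repeats
  c1 <- strsplit(substr(g$seq, rp$copy1_start, rp$copy1_end), "")[[1]]
  c2 <- strsplit(revcomp(substr(g$seq, rp$copy2_start, rp$copy2_end)), "")[[1]]
  expect_lte(sum(c1 != c2), 3)
  expect_gt(sum(c1 == c2), 700)
})

test_that("repeat spec validation rejects overlapping or misplaced copies", {
  expect_error(repeat_plant_spec(copy1_start = -900, copy2_start = -800),
               "overlap")
  expect_error(cluster_spec(repeat_plant = repeat_plant_spec(copy1_start = -7000),
                            promoter_len = 6000),
               "outside")
  expect_error(cluster_spec(gene_order = "PLE-1",
                            intron_sizes = list("PLE-1" = c(rep(100, 12), 3))),
               ">= 4")
})

test_that("point mutations spare splice sites, start/stop and primer 3' ends", {
  spec <- cluster_spec(gene_order = "PLE-1", point_mutation_rate = 0.01,
                       seed = 17)
  g <- generate_gene(spec, "PLE-1")
  intr <- g$truth$introns
  expect_true(all(substring(g$seq, intr$start, intr$start + 1) == "GT"))
  expect_true(all(substring(g$seq, intr$end - 1, intr$end) == "AG"))
  ex <- dplyr::arrange(g$truth$exons, exon)
  expect_equal(substr(g$seq, ex$start[1], ex$start[1] + 2), "ATG")
  # a 1% rate must actually have mutated something relative to rate 0
  g0 <- generate_gene(cluster_spec(gene_order = "PLE-1", seed = 17), "PLE-1")
  expect_false(identical(g$seq, g0$seq))
})

test_that("cluster length is the sum of gene units plus spacers", {
  spec <- cluster_spec(gene_order = c("PLE-G2", "PLE-1", "PLE-B9"),
                       seed = 1063)
  sim <- generate_cluster(spec)
  unit <- function(g) 6000 + 1698 + sum(intron_sizes_for(g)) + 200
  expect_equal(nchar(sim$seq),
               unit("PLE-G2") + unit("PLE-1") + unit("PLE-B9") + 2 * 22000)
  expect_equal(sim$truth$genes$gene_id, c("PLE-G2", "PLE-1", "PLE-B9"))
  expect_true(all(diff(sim$truth$genes$body_start) > 0))
})

test_that("single-gene cluster equals generate_gene output", {
  spec <- cluster_spec(gene_order = "PLE-1", seed = 12)
  expect_identical(generate_cluster(spec)$seq,
                   generate_gene(spec, "PLE-1")$seq)
})

test_that("BAC clone windows record vector placement and overlap truth", {
  locus <- with_seed(3, random_dna(30000))
  v <- ple_vector()
  wins <- data.frame(clone_id = c("a", "b", "c"),
                     start = c(1, 10000 - 6082 + 1, 25000),
                     end = c(10000, 20000, 30000))
  cl <- generate_bac_clones(locus, wins, v)
  expect_equal(nchar(cl$clones[["a"]]), 8128 + 10000)
  expect_identical(substr(cl$clones[["a"]], 1, 8128), v)
  ov <- cl$truth$overlaps
  expect_equal(ov$length[ov$cloneA == "a" & ov$cloneB == "b"], 6082L)
  expect_equal(ov$length[ov$cloneA == "b" & ov$cloneB == "c"], 0L)
  expect_error(generate_bac_clones(locus, data.frame(clone_id = "x",
                                                     start = 1, end = 40000)),
               "outside")
})

test_that("library planting: positives recorded, decoys primer-free, duplicates rejected", {
  clone <- mk_positive_clone(seed = 1063)
  pos <- data.frame(plate = c(1, 2, 2, 3, 4), row = c(1, 2, 3, 4, 5),
                    col = c(1, 2, 2, 3, 4), gene_id = "PLE-1")
  lay <- library_layout_spec(4, positives = pos, decoy_insert_len = 500)
  lib <- generate_library(lay, c("PLE-1" = clone), seed = 9)
  expect_equal(nrow(lib$wells), 4 * 384)
  expect_equal(nrow(lib$truth), 5)
  decoys <- dplyr::filter(lib$wells, is.na(gene_id))
  some <- decoys$sequence[1:50]
  panel <- screen_panel()
  for (r in seq_len(nrow(panel))) {
    amps <- insilico_pcr(stats::setNames(some, paste0("d", seq_along(some))),
                         panel[r, ])
    expect_equal(nrow(amps), 0)
  }
  expect_error(library_layout_spec(4, positives = rbind(pos, pos[1, ])),
               "duplicate")
  expect_error(library_layout_spec(2, positives = pos), "outside")
})
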