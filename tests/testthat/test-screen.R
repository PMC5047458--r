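test_that("constructed template gives the arithmetic product length", {
  pair <- ple_primers()[1, ]
  spacer <- strrep("N", 10)
  template <- paste0("ACGT", pair$forward, spacer, revcomp(pair$reverse),
                     "TTTT")
  amps <- insilico_pcr(template, pair)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, nchar(pair$forward) + 10L + nchar(pair$reverse))
  expect_equal(amps$start, 5L)
  expect_equal(amps$fwd_strand, "+")
  # the product is found regardless of template orientation
  amps_rc <- insilico_pcr(revcomp(template), pair)
  expect_equal(amps_rc$length, amps$length)
  expect_equal(amps_rc$fwd_strand, "-")
})

test_that("synthetic positive clone amplifies the published product sizes", {
  clone <- mk_positive_clone(seed = 1063)
  p <- ple_primers()
  expect_equal(insilico_pcr(clone, p[1, ])$length, 208L)
  expect_equal(insilico_pcr(clone, p[2, ])$length, 534L)
  # decoy template yields nothing
  decoy <- with_seed(77, random_dna(5000))
  expect_equal(nrow(insilico_pcr(decoy, p[1, ])), 0)
})

test_that("products beyond max_product or with unpaired primers are not called", {
  pair <- ple_primers()[1, ]
  far <- paste0(pair$forward, random_dna(12000), revcomp(pair$reverse))
  expect_equal(nrow(insilico_pcr(far, pair, max_product = 10000)), 0)
  fwd_only <- paste0(random_dna(100), pair$forward, random_dna(100))
  expect_equal(nrow(insilico_pcr(fwd_only, pair)), 0)
})

test_that("mismatch tolerance honours the exact 3'-end requirement", {
  pair <- ple_primers()[1, ]
  fwd <- pair$forward
  # mutate one base in the 5' half of the forward primer site
  site <- fwd
  substr(site, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(site, 3, 3))[1]
  template <- paste0("AAAA", site, strrep("T", 50), revcomp(pair$reverse))
  expect_equal(nrow(insilico_pcr(template, pair, max_mismatch = 0)), 0)
  expect_equal(nrow(insilico_pcr(template, pair, max_mismatch = 1)), 1)
  # the same mutation in the 3'-terminal block kills the primer
  site2 <- fwd
  pl <- nchar(fwd)
  substr(site2, pl - 1, pl - 1) <- setdiff(c("A", "C", "G", "T"),
                                           substr(site2, pl - 1, pl - 1))[1]
  template2 <- paste0("AAAA", site2, strrep("T", 50), revcomp(pair$reverse))
  expect_equal(nrow(insilico_pcr(template2, pair, max_mismatch = 1)), 0)
})

test_that("pool positivity is an OR over members and monotone under growth", {
  clone <- mk_positive_clone(seed = 1063)
  panel <- screen_panel()
  decoys <- with_seed(88, vapply(1:6, function(i) random_dna(1000),
                                 character(1)))
  names(decoys) <- paste0("d", 1:6)
  expect_false(plegenes:::pool_positive(decoys, panel))
  expect_true(plegenes:::pool_positive(c(decoys, pos = clone), panel))
  # every subset containing the positive is positive
  for (k in 0:3) {
    subset <- c(decoys[seq_len(k)], pos = clone)
    expect_true(plegenes:::pool_positive(subset, panel))
  }
  amps <- insilico_pcr(pool(c(decoys, pos = clone)), panel[1, ])
  expect_equal(unique(amps$template_id), "pos")
})

test_that("three-step screen recovers exactly the planted wells", {
  clone <- mk_positive_clone(seed = 1063)
  pos <- data.frame(plate = c(2, 5, 5, 9, 14), row = c(3, 1, 16, 8, 12),
                    col = c(7, 20, 20, 1, 24), gene_id = "PLE-1")
  lay <- library_layout_spec(15, positives = pos, decoy_insert_len = 1000)
  lib <- generate_library(lay, c("PLE-1" = clone), seed = 21)
  res <- run_three_step_screen(lib)
  expect_equal(res$step1_positive_plates, c(2, 5, 9, 14))
  found <- dplyr::arrange(res$step3_positive_wells, plate, row, col)
  expect_equal(nrow(found), 5)
  expect_equal(found$plate, sort(pos$plate))
  truth <- dplyr::arrange(lib$truth, plate, row, col)
  expect_equal(found$well_id, truth$well_id)
  # hierarchy: wells within pools within plates
  expect_true(all(res$step3_positive_wells$plate %in% res$step1_positive_plates))
  expect_true(all(paste(res$step3_positive_wells$plate,
                        res$step3_positive_wells$col) %in%
                    paste(res$step2_positive_pools$plate,
                          res$step2_positive_pools$col)))
  # pooled design uses far fewer reactions than well-by-well PCR
  expect_equal(res$pcr_count, 15 + 24 * 4 + 16 * 4)
  expect_lt(res$pcr_count, 384 * 15)
})

test_that("a decoy-only library screens negative", {
  lay <- library_layout_spec(5, decoy_insert_len = 800)
  lib <- generate_library(lay, seed = 31)
  res <- run_three_step_screen(lib)
  expect_equal(length(res$step1_positive_plates), 0)
  expect_equal(nrow(res$step2_positive_pools), 0)
  expect_equal(nrow(res$step3_positive_wells), 0)
})

test_that("primer panel verification mirrors bench acceptance and rejection", {
  clone <- mk_positive_clone(seed = 1063)
  decoys <- with_seed(55, c(d1 = random_dna(2000), d2 = random_dna(2000)))
  p <- ple_primers()
  report <- verify_primer_panel(p[1:3, ], c(pos = clone), decoys)
  expect_equal(report$status[report$id == 1], "usable")
  expect_equal(report$products[[1]], 208)
  expect_equal(report$status[report$id == 2], "usable")
  # pair 3's forward primer has no planted site: no product, rejected
  expect_equal(report$status[report$id == 3], "rejected_no_product")
})

test_that("a pair amplifying two distinct sizes reports both", {
  pair <- ple_primers()[4, ]
  cassette <- function(size) {
    paste0(pair$forward,
           random_dna(size - nchar(pair$forward) - nchar(pair$reverse)),
           revcomp(pair$reverse))
  }
  template <- with_seed(66, paste0(cassette(2327), random_dna(8000),
                                   cassette(3811)))
  report <- verify_primer_panel(pair, c(t1 = template))
  expect_equal(report$products[[1]], c(2327, 3811))
  expect_equal(report$status, "usable")
})

test_that("off-size-only products are rejected", {
  pair <- ple_primers()[1, ]  # expects 208
  template <- with_seed(67, paste0(pair$forward, random_dna(1000),
                                   revcomp(pair$reverse)))
  report <- verify_primer_panel(pair, c(t1 = template))
  expect_equal(report$status, "rejected_off_size")
})
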