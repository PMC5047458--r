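test_that("vector trimming recovers the windowed insert wherever the vector sits", {
  locus <- with_seed(41, random_dna(20000))
  v <- ple_vector()
  insert <- substr(locus, 2001, 12000)
  expect_identical(trim_vector(paste0(v, insert))$insert, insert)
  expect_identical(trim_vector(paste0(insert, v))$insert, insert)
  mid <- trim_vector(paste0(substr(insert, 1, 4000), v,
                            substr(insert, 4001, 10000)))
  expect_identical(mid$insert, insert)
  expect_true(mid$vector_found)
  expect_equal(mid$vector_interval[1], 4001)
})

test_that("vector-free input is returned unchanged with a warning flag", {
  s <- with_seed(42, random_dna(5000))
  expect_warning(res <- trim_vector(s), "no vector")
  expect_identical(res$insert, s)
  expect_false(res$vector_found)
})

test_that("overlap detection matches the exact window intersections", {
  locus <- with_seed(43, random_dna(40000))
  wins <- data.frame(clone_id = c("a", "b", "c"),
                     start = c(1, 9919, 30000),
                     end = c(16000, 26000, 40000))
  cl <- generate_bac_clones(locus, wins)
  inserts <- vapply(cl$clones, function(s) trim_vector(s)$insert, character(1))
  ov <- pairwise_overlaps(inserts, min_overlap = 2000)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 16000 - 9919 + 1)  # 6082, the published overlap
  expect_equal(ov$identity, 100)
  expect_equal(ov$cloneA, "a")
  expect_equal(ov$endA, "3p")
  expect_equal(ov$endB, "5p")
})

test_that("a clone against its own copy gives a full-length 100% overlap", {
  s <- with_seed(44, random_dna(12000))
  ov <- pairwise_overlaps(c(x = s, y = s), min_overlap = 2000)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 12000)
  expect_equal(ov$identity, 100)
})

test_that("disjoint clones yield no overlap", {
  a <- with_seed(45, random_dna(10000))
  b <- with_seed(46, random_dna(10000))
  expect_equal(nrow(pairwise_overlaps(c(a = a, b = b))), 0)
})

test_that("clone ordering reconstructs the layout and reads off gene order", {
  panel <- generate_clone_panel(seed = 1063)
  inserts <- vapply(panel$clones, function(s) trim_vector(s)$insert,
                    character(1))
  ov <- pairwise_overlaps(inserts)
  # gene positions from the generator truth, per clone window
  truth_genes <- panel$truth$cluster1$genes
  wins <- panel$windows$cluster1
  clone_genes <- do.call(rbind, lapply(seq_len(nrow(wins)), function(k) {
    w <- wins[k, ]
    hit <- truth_genes[truth_genes$body_start >= w$start &
                         truth_genes$body_end <= w$end, ]
    if (nrow(hit) == 0) return(NULL)
    data.frame(clone_id = w$clone_id, gene_id = hit$gene_id,
               position = (hit$body_start + hit$body_end) / 2 - w$start + 1)
  }))
  clone_genes <- rbind(clone_genes,
                       data.frame(clone_id = "BAC-119", gene_id = "PLE-C4",
                                  position = 20000))
  clusters <- order_clones(ov, clone_genes, vapply(inserts, nchar, integer(1)))
  expect_equal(length(clusters), 2)
  sizes <- vapply(clusters, function(cl) nrow(cl$clones), integer(1))
  main <- clusters[[which.max(sizes)]]
  expect_equal(main$genes, c("PLE-G2", "PLE-1", "PLE-B9"))
  expect_equal(main$clones$clone_id,
               c("BAC-10", "BAC-206", "BAC-70", "BAC-75"))
  # offsets reconstruct the master locus span exactly at rate 0
  lens <- vapply(inserts, nchar, integer(1))
  span <- max(main$clones$offset + lens[main$clones$clone_id])
  expect_equal(span, nchar(panel$loci$cluster1))
})

test_that("ordering is invariant to input order and to reverse-complementing a clone", {
  locus <- with_seed(47, random_dna(50000))
  wins <- data.frame(clone_id = c("c1", "c2", "c3"),
                     start = c(1, 15001, 32001),
                     end = c(20000, 37000, 50000))
  inserts <- stats::setNames(substring(locus, wins$start, wins$end),
                             wins$clone_id)
  genes <- data.frame(clone_id = c("c1", "c2", "c3"),
                      gene_id = c("gA", "gB", "gC"),
                      position = c(5000, 10000, 12000))
  lens <- vapply(inserts, nchar, integer(1))
  base <- order_clones(pairwise_overlaps(inserts), genes, lens)

  shuffled <- inserts[c(3, 1, 2)]
  alt <- order_clones(pairwise_overlaps(shuffled), genes, lens[c(3, 1, 2)])
  expect_equal(base[[1]]$genes, alt[[1]]$genes)

  flipped <- inserts
  flipped[["c2"]] <- revcomp(flipped[["c2"]])
  ovf <- pairwise_overlaps(flipped)
  expect_true("-" %in% ovf$orientation)
  altf <- order_clones(ovf, genes, lens)
  expect_equal(altf[[1]]$genes, base[[1]]$genes)
  expect_equal(altf[[1]]$clones$orientation[altf[[1]]$clones$clone_id == "c2"],
               "-")
  expect_equal(dplyr::arrange(altf[[1]]$clones, clone_id)$offset,
               dplyr::arrange(base[[1]]$clones, clone_id)$offset)
})

test_that("branching overlap graphs are refused with the clones named", {
  ov <- tibble::tibble(
    cloneA = c("a", "a", "a"), cloneB = c("b", "c", "d"),
    endA = "3p", endB = "5p", orientation = "+",
    diagonal = c(1000L, 2000L, 3000L), length = 5000L, identity = 100,
    gaps = 0L)
  lens <- c(a = 10000L, b = 10000L, c = 10000L, d = 10000L)
  genes <- data.frame(clone_id = "a", gene_id = "g", position = 1)
  expect_error(order_clones(ov, genes, lens), "branching.*a")
})

test_that("a single clone forms a singleton cluster", {
  genes <- data.frame(clone_id = "only", gene_id = "gX", position = 500)
  ov <- pairwise_overlaps(c(only = with_seed(48, random_dna(5000)),
                            other = with_seed(49, random_dna(5000))))
  clusters <- order_clones(ov, genes, c(only = 5000L, other = 5000L))
  expect_equal(length(clusters), 2)
  expect_equal(clusters[[1]]$clones$clone_id, "only")
  expect_equal(clusters[[1]]$genes, "gX")
})
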