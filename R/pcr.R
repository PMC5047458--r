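# In-silico PCR: exact (optionally mismatch-tolerant) primer matching on
# both strands with 3'-end protection, and amplicon enumeration.

primer_hits <- function(primer, template_dna, max_mismatch, three_prime_exact,
                        three_prime_side) {
  hits <- Biostrings::matchPattern(primer, template_dna,
                                   max.mismatch = max_mismatch)
  if (length(hits) == 0 || max_mismatch == 0) return(hits)
  # enforce an exact 3'-terminal block (extension end of the primer)
  keep <- vapply(seq_along(hits), function(k) {
    hv <- as.character(hits[[k]])
    pl <- nchar(primer)
    idxs <- if (three_prime_side == "right") (pl - three_prime_exact + 1L):pl
            else 1L:three_prime_exact
    substr(hv, min(idxs), max(idxs)) == substr(primer, min(idxs), max(idxs))
  }, logical(1))
  hits[keep]
}

empty_amplicons <- function() {
  tibble(template_id = character(), start = integer(), end = integer(),
         length = integer(), fwd_strand = character())
}

#' Predict PCR products on a template
#'
#' Finds all binding sites of the forward and reverse primer on both strands
#' and reports every convergent primer-pair placement within `max_product`.
#' Product coordinates are 1-based inclusive and include both primers.
#' Primer matching is exact by default; with `max_mismatch > 0`, mismatches
#' are still forbidden within the `three_prime_exact` 3'-terminal bases
#' (polymerase extension requires a matched 3' end).
#'
#' @param template Template sequence (character) or a named character vector
#'   of templates / a [pool()] of them.
#' @param pair One row of [ple_primers()] (or any list with `forward`,
#'   `reverse`).
#' @param max_product Maximum product length (nt).
#' @param max_mismatch Mismatches tolerated per primer site.
#' @param three_prime_exact 3'-terminal bases that must match exactly.
#' @return A tibble of amplicons: `template_id`, `start`, `end`, `length`,
#'   `fwd_strand` ("+" if the forward primer sits on the plus strand),
#'   sorted by position. Empty tibble if there is no product.
#' @export
insilico_pcr <- function(template, pair, max_product = 10000L,
                         max_mismatch = 0L, three_prime_exact = 5L) {
  if (inherits(template, "pcr_pool")) template <- template$sequences
  ids <- names(template) %||% rep("template", length(template))
  out <- purrr::map2(as.list(template), ids, function(seq, id) {
    dna <- Biostrings::DNAString(seq)
    fwd <- pair$forward
    rev <- pair$reverse
    rows <- list()
    # forward primer on plus strand + reverse primer on minus strand
    f_plus <- primer_hits(fwd, dna, max_mismatch, three_prime_exact, "right")
    r_minus <- primer_hits(revcomp(rev), dna, max_mismatch, three_prime_exact,
                           "left")
    if (length(f_plus) > 0 && length(r_minus) > 0) {
      for (s in Biostrings::start(f_plus)) {
        for (e in Biostrings::end(r_minus)) {
          len <- e - s + 1L
          if (e >= s + nchar(fwd) + nchar(rev) - 1L && len <= max_product) {
            rows[[length(rows) + 1L]] <-
              tibble(template_id = id, start = s, end = e, length = len,
                     fwd_strand = "+")
          }
        }
      }
    }
    # forward primer on minus strand + reverse primer on plus strand
    r_plus <- primer_hits(rev, dna, max_mismatch, three_prime_exact, "right")
    f_minus <- primer_hits(revcomp(fwd), dna, max_mismatch, three_prime_exact,
                           "left")
    if (length(r_plus) > 0 && length(f_minus) > 0) {
      for (s in Biostrings::start(r_plus)) {
        for (e in Biostrings::end(f_minus)) {
          len <- e - s + 1L
          if (e >= s + nchar(fwd) + nchar(rev) - 1L && len <= max_product) {
            rows[[length(rows) + 1L]] <-
              tibble(template_id = id, start = s, end = e, length = len,
                     fwd_strand = "-")
          }
        }
      }
    }
    if (length(rows) == 0) empty_amplicons() else dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out) |> arrange(template_id, start, end)
}

#' Pool templates for a screening reaction
#'
#' A pool is positive for a primer pair iff any member template yields an
#' amplicon; [insilico_pcr()] accepts pools directly.
#'
#' @param sequences Named character vector of member templates.
#' @return An object of class `pcr_pool`.
#' @export
pool <- function(sequences) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("member", seq_along(sequences))
  }
  structure(list(sequences = sequences), class = "pcr_pool")
}

#' @export
print.pcr_pool <- function(x, ...) {
  cat(sprintf("<pcr_pool> %d templates\n", length(x$sequences)))
  invisible(x)
}

# Does any member of `seqs` produce an expected-size product for any panel
# pair? `candidates` (well ids with a possible primer site, from the k-mer
# prefilter) short-circuits the full PCR to the wells that can amplify.
pool_positive <- function(seqs, panel, size_tol = 0.05, candidates = NULL) {
  test_ids <- if (is.null(candidates)) names(seqs) else
    intersect(names(seqs), candidates)
  for (id in test_ids) {
    for (r in seq_len(nrow(panel))) {
      pair <- panel[r, ]
      amps <- insilico_pcr(stats::setNames(seqs[id], id), pair)
      if (nrow(amps) == 0) next
      exp_sizes <- pair$expected_products[[1]]
      ok <- vapply(amps$length, function(L) {
        any(abs(L - exp_sizes) <= size_tol * exp_sizes)
      }, logical(1))
      if (any(ok)) return(TRUE)
    }
  }
  FALSE
}

# Wells whose sequence contains any panel primer in either orientation;
# everything else cannot yield a product at max_mismatch = 0.
possible_positive_wells <- function(wells, panel) {
  set <- Biostrings::DNAStringSet(wells$sequence)
  pats <- unique(c(panel$forward, panel$reverse,
                   revcomp(panel$forward), revcomp(panel$reverse)))
  hit <- rep(FALSE, nrow(wells))
  for (p in pats) hit <- hit | (Biostrings::vcountPattern(p, set) > 0)
  wells$well_id[hit]
}

#' Run the three-step pooled PCR screen
#'
#' Step 1 screens one pooled template per plate; step 2 splits each positive
#' plate into 24 pools of 16 wells (one per plate column); step 3 screens
#' the single wells of each positive pool. A template is called positive
#' when any panel pair yields a product within `size_tol` of one of its
#' expected sizes (gel-style size calling).
#'
#' @param library Library from [generate_library()].
#' @param panel Primer panel (rows of [ple_primers()]); defaults to the
#'   single-product screening pairs 1 and 2.
#' @param size_tol Relative product-size acceptance window.
#' @return An object of class `screen_result`: tibbles of positive plates,
#'   pools and wells, and `pcr_count`, the number of pooled/single templates
#'   amplified (cf. 384 x n_plates reactions for a naive well-by-well
#'   screen).
#' @export
run_three_step_screen <- function(library,
                                  panel = ple_primers() |> filter(id %in% c(1L, 2L)),
                                  size_tol = 0.05) {
  wells <- library$wells
  candidates <- possible_positive_wells(wells, panel)
  pcr_count <- 0L
  plates <- sort(unique(wells$plate))
  step1 <- integer(0)
  for (p in plates) {
    pw <- wells |> filter(plate == p)
    pcr_count <- pcr_count + 1L
    if (pool_positive(stats::setNames(pw$sequence, pw$well_id), panel,
                      size_tol, candidates)) {
      step1 <- c(step1, p)
    }
  }
  step2 <- tibble(plate = integer(), col = integer())
  for (p in step1) {
    for (cc in sort(unique(wells$col))) {
      cw <- wells |> filter(plate == p, col == cc)
      pcr_count <- pcr_count + 1L
      if (pool_positive(stats::setNames(cw$sequence, cw$well_id), panel,
                        size_tol, candidates)) {
        step2 <- dplyr::bind_rows(step2, tibble(plate = p, col = cc))
      }
    }
  }
  step3 <- tibble(plate = integer(), row = integer(), col = integer(),
                  well_id = character())
  for (r in seq_len(nrow(step2))) {
    sw <- wells |> filter(plate == step2$plate[r], col == step2$col[r])
    for (k in seq_len(nrow(sw))) {
      pcr_count <- pcr_count + 1L
      if (pool_positive(stats::setNames(sw$sequence[k], sw$well_id[k]), panel,
                        size_tol, candidates)) {
        step3 <- dplyr::bind_rows(step3, sw[k, c("plate", "row", "col", "well_id")])
      }
    }
  }
  structure(list(step1_positive_plates = step1,
                 step2_positive_pools = step2,
                 step3_positive_wells = step3,
                 pcr_count = pcr_count,
                 n_plates = length(plates)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("<screen_result> %d positive plate(s), %d positive ",
                     "pool(s), %d positive well(s); %d PCR template(s) ",
                     "amplified\n"),
              length(x$step1_positive_plates), nrow(x$step2_positive_pools),
              nrow(x$step3_positive_wells), x$pcr_count))
  invisible(x)
}

#' @export
tidy.screen_result <- function(x, ...) x$step3_positive_wells

#' @export
glance.screen_result <- function(x, ...) {
  tibble(positive_plates = length(x$step1_positive_plates),
         positive_pools = nrow(x$step2_positive_pools),
         positive_wells = nrow(x$step3_positive_wells),
         pcr_count = x$pcr_count,
         naive_pcr_count = 384L * x$n_plates)
}

#' Verify a primer panel against positives and decoys
#'
#' Mirrors bench primer validation: each pair is run against the positive
#' templates and the decoys; pairs with no product or only off-size products
#' are rejected, pairs amplifying on decoys are flagged non-specific, and
#' all observed product sizes are reported (pairs may legitimately yield
#' two product sizes when intron sizes differ between gene copies).
#'
#' @param panel Primer panel rows ([ple_primers()] shape).
#' @param positive_templates Named character vector of gene-carrying
#'   templates.
#' @param decoys Named character vector of negative templates.
#' @param size_tol Relative product-size acceptance window.
#' @return A tibble: `id`, `products` (list of sizes on positives),
#'   `decoy_products`, `status` ("usable", "rejected_no_product",
#'   "rejected_off_size", "rejected_nonspecific").
#' @export
verify_primer_panel <- function(panel, positive_templates,
                                decoys = character(0), size_tol = 0.05) {
  purrr::map(seq_len(nrow(panel)), function(r) {
    pair <- panel[r, ]
    pos_amp <- insilico_pcr(positive_templates, pair)
    dec_amp <- if (length(decoys) > 0) insilico_pcr(decoys, pair) else
      empty_amplicons()
    sizes <- sort(unique(pos_amp$length))
    exp_sizes <- pair$expected_products[[1]]
    on_size <- any(vapply(sizes, function(L) {
      any(abs(L - exp_sizes) <= size_tol * exp_sizes)
    }, logical(1)))
    status <- if (nrow(dec_amp) > 0) "rejected_nonspecific"
      else if (length(sizes) == 0) "rejected_no_product"
      else if (!on_size) "rejected_off_size"
      else "usable"
    tibble(id = pair$id, products = list(sizes),
           decoy_products = list(sort(unique(dec_amp$length))),
           status = status)
  }) |> dplyr::bind_rows()
}
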