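# Synthetic PLE-like locus generator. Everything is driven by the bundled
# printed tables so that every downstream stage can be validated against a
# known ground truth without any external data.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc != "*"])
})

codon_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cands <- names(gc[gc == aa])
  if (length(cands) == 0) abort(sprintf("no codon encodes residue '%s'", aa))
  sample(cands, 1)
}

# Codon for `aa` with the fewest nucleotide changes from `original`
# (deterministic on ties). Isoforms of one family diverge by point
# mutations, so a recoded diagnostic codon should stay as close as possible
# to the ancestral codon.
codon_nearest <- function(aa, original) {
  gc <- Biostrings::GENETIC_CODE
  cands <- sort(names(gc[gc == aa]))
  if (length(cands) == 0) abort(sprintf("no codon encodes residue '%s'", aa))
  ov <- chars(original)
  dist <- vapply(cands, function(cc) sum(chars(cc) != ov), integer(1))
  cands[which.min(dist)]
}

#' Generate a coding sequence partitioned into exons
#'
#' Builds a random-composition CDS that starts with ATG, ends with a single
#' stop codon and contains no internal stops, then partitions it into the
#' requested exon sizes. Residues can be planted at specific amino-acid
#' positions (full-length numbering = mature position + 18) so that the
#' translation realises a chosen diagnostic-residue profile, and the
#' C-terminal tetrapeptide defaults to the ER-retention signal HAEL.
#'
#' @param exon_sizes Integer vector of exon sizes (nt); must sum to a
#'   multiple of 3 (and at least 6).
#' @param seed RNG seed.
#' @param profile Optional named character vector of residues keyed by
#'   mature-peptide position (as from [diagnostic_column()]); planted at
#'   full-length position `position + 18`.
#' @param c_terminal Four-residue C-terminal motif to plant, or NULL to
#'   leave the C terminus random. Ignored for proteins shorter than 22 aa.
#' @return A list with `cdna` (character CDS), `boundaries` (tibble of
#'   per-exon `start`/`end` on the CDS) and `protein` (character).
#' @export
generate_cdna <- function(exon_sizes, seed = DEFAULT_SEED, profile = NULL,
                          c_terminal = "HAEL") {
  exon_sizes <- as.integer(exon_sizes)
  total <- sum(exon_sizes)
  if (total %% 3L != 0L) abort("exon sizes must sum to a multiple of 3")
  if (total < 6L) abort("CDS must be at least 6 nt (start + stop)")
  n_codons <- total %/% 3L
  with_seed(seed, {
    codons <- c("ATG",
                if (n_codons > 2L) sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                "TAA")
    n_aa <- n_codons - 1L  # stop excluded
    if (!is.null(c_terminal) && n_aa >= 22L) {
      stopifnot(nchar(c_terminal) == 4L)
      aa <- chars(c_terminal)
      for (k in seq_along(aa)) {
        pos <- n_aa - 4L + k
        if (pos > 1L) codons[pos] <- codon_for(aa[k])
      }
    }
    if (!is.null(profile)) {
      full_pos <- as.integer(names(profile)) + 18L
      if (any(full_pos > n_aa)) abort("profile position beyond protein length")
      for (k in seq_along(full_pos)) {
        if (full_pos[k] == 1L) next
        codons[full_pos[k]] <- codon_for(profile[[k]])
      }
    }
    cdna <- paste(codons, collapse = "")
    ends <- cumsum(exon_sizes)
    list(cdna = cdna,
         boundaries = tibble(exon = seq_along(exon_sizes),
                             start = ends - exon_sizes + 1L, end = ends),
         protein = as.character(Biostrings::translate(
           Biostrings::DNAString(substr(cdna, 1, total - 3L)))))
  })
}

# Amplicon cassette for one bundled primer pair: forward primer, random
# spacer sized so the product matches the first expected size, reverse
# primer site (reverse complement of the reverse primer).
primer_cassette <- function(pair) {
  product <- pair$expected_products[[1]][1]
  spacer <- product - nchar(pair$forward) - nchar(pair$reverse)
  if (spacer < 0) abort("expected product shorter than the two primers")
  paste0(pair$forward, random_dna(spacer), revcomp(pair$reverse))
}

# One intron: GT + random interior + AG, with an optional planted cassette
# starting at interior offset `cas_at` (1-based position within the intron).
make_intron <- function(len, cassette = NULL, cas_at = 101L) {
  s <- paste0("GT", random_dna(len - 4L), "AG")
  cas_len <- 0L
  if (!is.null(cassette)) {
    cas_len <- nchar(cassette)
    if (cas_at < 3L || cas_at + cas_len - 1L > len - 2L) {
      abort("planted primer cassette does not fit inside the intron")
    }
    substr(s, cas_at, cas_at + cas_len - 1L) <- cassette
  }
  s
}

# Build one gene unit (promoter + gene body + 200 nt downstream) on the plus
# strand, together with its ground truth in unit coordinates; then apply
# point mutations and, if requested, flip to the minus strand.
gene_unit <- function(spec, gene_id, cdna_rec) {
  exon_sizes <- spec$exon_sizes
  intron_sizes <- spec$intron_sizes[[gene_id]]
  n_ex <- length(exon_sizes)
  promoter_len <- spec$promoter_len

  # per-gene CDS: recode diagnostic positions where this isoform differs
  cds <- cdna_rec$cdna
  diag_tbl <- ple_diagnostics()
  diag_codons <- integer(0)
  if (gene_id %in% names(diag_tbl) &&
      nchar(cds) >= 3L * (max(diag_tbl$position) + 18L)) {
    want <- diagnostic_column(gene_id)
    have <- cdna_rec$profile %||% diagnostic_column("gamma-PLE")
    full_pos <- as.integer(names(want)) + 18L
    for (k in seq_along(want)) {
      p <- full_pos[k]
      if (want[[k]] != have[[k]]) {
        substr(cds, 3L * p - 2L, 3L * p) <-
          codon_nearest(want[[k]], substr(cds, 3L * p - 2L, 3L * p))
      }
      diag_codons <- c(diag_codons, (3L * p - 2L):(3L * p))
    }
  }

  # promoter with the planted inverted-repeat pair
  rp <- spec$repeat_plant
  promoter <- random_dna(promoter_len)
  copy1 <- random_dna(rp$length)
  copy2 <- revcomp(copy1)
  if (rp$max_mismatches > 0L) {
    at <- sample(rp$length, min(rp$max_mismatches, rp$length))
    for (i in at) {
      substr(copy2, i, i) <- sample(setdiff(DNA_BASES, substr(copy2, i, i)), 1)
    }
  }
  i1 <- promoter_index(rp$copy1_start, promoter_len)
  i2 <- promoter_index(rp$copy2_start, promoter_len)
  substr(promoter, i1, i1 + rp$length - 1L) <- copy1
  substr(promoter, i2, i2 + rp$length - 1L) <- copy2
  # boundary guards: force a mismatch just outside both arms so the planted
  # pair is exactly maximal (random flanks would otherwise extend it by
  # chance complementarity)
  ge1 <- i1 + rp$length  # right of copy1, pairs with base left of copy2
  gs2 <- i2 - 1L
  if (ge1 <= promoter_len && gs2 >= 1L &&
      substr(promoter, gs2, gs2) == revcomp(substr(promoter, ge1, ge1))) {
    substr(promoter, gs2, gs2) <-
      sample(setdiff(DNA_BASES, revcomp(substr(promoter, ge1, ge1))), 1)
  }
  gs1 <- i1 - 1L  # left of copy1, pairs with base right of copy2
  ge2 <- i2 + rp$length
  if (gs1 >= 1L && ge2 <= promoter_len &&
      substr(promoter, gs1, gs1) == revcomp(substr(promoter, ge2, ge2))) {
    substr(promoter, gs1, gs1) <-
      sample(setdiff(DNA_BASES, revcomp(substr(promoter, ge2, ge2))), 1)
  }

  # planted primer cassettes: pair id k goes into intron k
  primers <- ple_primers()
  cassettes <- vector("list", n_ex - 1L)
  for (pid in spec$plant_primers) {
    if (pid >= 1L && pid <= n_ex - 1L) {
      cassettes[[pid]] <- primer_cassette(primers[primers$id == pid, ])
    }
  }

  # interleave exons and introns
  exon_seq <- substring(cds,
                        cdna_rec$boundaries$start, cdna_rec$boundaries$end)
  introns <- purrr::map2_chr(as.list(intron_sizes), cassettes,
                             function(len, cas) make_intron(len, cas))
  body <- character(2L * n_ex - 1L)
  body[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_seq
  body[seq(2L, 2L * n_ex - 2L, by = 2L)] <- introns
  unit <- paste0(promoter, paste(body, collapse = ""), random_dna(200L))
  unit_len <- nchar(unit)

  # ground-truth intervals (unit coordinates, plus strand)
  piece_len <- integer(2L * n_ex - 1L)
  piece_len[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_sizes
  piece_len[seq(2L, 2L * n_ex - 2L, by = 2L)] <- intron_sizes
  piece_end <- promoter_len + cumsum(piece_len)
  piece_start <- piece_end - piece_len + 1L
  ex_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
  in_idx <- seq(2L, 2L * n_ex - 2L, by = 2L)
  exons <- tibble(gene_id = gene_id, exon = seq_len(n_ex),
                  start = piece_start[ex_idx], end = piece_end[ex_idx])
  intr <- tibble(gene_id = gene_id, intron = seq_len(n_ex - 1L),
                 start = piece_start[in_idx], end = piece_end[in_idx])

  prim_rows <- purrr::compact(purrr::imap(cassettes, function(cas, k) {
    if (is.null(cas)) return(NULL)
    st <- intr$start[k] + 100L
    tibble(gene_id = gene_id, pair_id = k, start = st,
           end = st + nchar(cas) - 1L, product_len = nchar(cas))
  }))
  prim <- if (length(prim_rows)) dplyr::bind_rows(prim_rows) else
    tibble(gene_id = character(), pair_id = integer(), start = integer(),
           end = integer(), product_len = integer())

  reps <- tibble(gene_id = gene_id,
                 copy1_start = i1, copy1_end = i1 + rp$length - 1L,
                 copy2_start = i2, copy2_end = i2 + rp$length - 1L,
                 length = rp$length, mismatches = rp$max_mismatches)

  # point mutations, avoiding forced motifs: splice dinucleotides, start and
  # stop codons, diagnostic codons, and the 3'-terminal 5 nt of every planted
  # primer site (in template orientation, the reverse site's 3' end is the
  # start of the reverse-complemented primer)
  if (spec$point_mutation_rate > 0) {
    protected <- c(
      unlist(lapply(in_idx, function(k) {
        c(piece_start[k], piece_start[k] + 1L, piece_end[k] - 1L, piece_end[k])
      })),
      exons$start[1]:(exons$start[1] + 2L),
      (exons$end[n_ex] - 2L):exons$end[n_ex]
    )
    if (nrow(prim) > 0) {
      for (r in seq_len(nrow(prim))) {
        pair <- primers[primers$id == prim$pair_id[r], ]
        fl <- nchar(pair$forward)
        rl <- nchar(pair$reverse)
        rev_site_start <- prim$end[r] - rl + 1L
        protected <- c(protected,
                       (prim$start[r] + fl - 5L):(prim$start[r] + fl - 1L),
                       rev_site_start:(rev_site_start + 4L))
      }
    }
    if (length(diag_codons) > 0) {
      protected <- c(protected, cds_to_unit(diag_codons, exons))
    }
    hit <- which(stats::runif(unit_len) < spec$point_mutation_rate)
    hit <- setdiff(hit, protected)
    for (i in hit) {
      substr(unit, i, i) <- sample(setdiff(DNA_BASES, substr(unit, i, i)), 1)
    }
  }

  genes <- tibble(gene_id = gene_id, strand = "+",
                  unit_start = 1L, unit_end = unit_len,
                  body_start = exons$start[1], body_end = exons$end[n_ex],
                  promoter_start = 1L, promoter_end = promoter_len)

  truth <- list(genes = genes, exons = exons, introns = intr,
                repeats = reps, primer_sites = prim,
                cds = stats::setNames(list(cds), gene_id))

  if (spec$gene_strands[[gene_id]] == "-") {
    unit <- revcomp(unit)
    flip <- function(tb) {
      if (nrow(tb) == 0 || !all(c("start", "end") %in% names(tb))) return(tb)
      ns <- unit_len - tb$end + 1L
      ne <- unit_len - tb$start + 1L
      tb$start <- ns; tb$end <- ne
      tb
    }
    truth$exons <- flip(truth$exons)
    truth$introns <- flip(truth$introns)
    truth$primer_sites <- flip(truth$primer_sites)
    rp_tb <- truth$repeats
    truth$repeats <- rp_tb |>
      mutate(copy1_start = unit_len - rp_tb$copy2_end + 1L,
             copy1_end = unit_len - rp_tb$copy2_start + 1L,
             copy2_start = unit_len - rp_tb$copy1_end + 1L,
             copy2_end = unit_len - rp_tb$copy1_start + 1L)
    truth$genes$strand <- "-"
    truth$genes$body_start <- unit_len - genes$body_end + 1L
    truth$genes$body_end <- unit_len - genes$body_start + 1L
    truth$genes$promoter_start <- unit_len - promoter_len + 1L
    truth$genes$promoter_end <- unit_len
  }
  list(seq = unit, truth = truth)
}

# Map CDS coordinates to unit coordinates through the exon intervals.
cds_to_unit <- function(cds_pos, exons) {
  sizes <- exons$end - exons$start + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ex <- findInterval(cds_pos, starts)
  exons$start[ex] + (cds_pos - starts[ex])
}

#' Generate a single synthetic PLE-like gene
#'
#' Emits one gene unit: `promoter_len` nt of promoter carrying the planted
#' inverted-repeat pair, the exon/intron structure with every intron
#' GT...AG-flanked, planted primer-amplicon cassettes, and 200 nt of
#' downstream sequence, together with the ground truth of all planted
#' features.
#'
#' @param spec A [cluster_spec()]; the RNG seed and all sizes come from it.
#' @param gene_id Gene to generate (must appear in `spec$gene_order`).
#' @return A list with `seq` (character), `truth` (list of tibbles:
#'   `genes`, `exons`, `introns`, `repeats`, `primer_sites`, plus `cds`),
#'   `cdna` (the reference CDS used to build the exons) and `boundaries`.
#' @export
generate_gene <- function(spec, gene_id = spec$gene_order[1]) {
  if (!gene_id %in% spec$gene_order) abort("gene_id not in spec$gene_order")
  with_seed(spec$seed, {
    cdna_rec <- generate_cdna_unseeded(spec$exon_sizes)
    unit <- gene_unit(spec, gene_id, cdna_rec)
    c(unit, list(cdna = cdna_rec$cdna, boundaries = cdna_rec$boundaries))
  })
}

# generate_cdna() body without the seed wrapper, for use inside a larger
# seeded generation; plants the gamma-PLE diagnostic profile.
generate_cdna_unseeded <- function(exon_sizes) {
  exon_sizes <- as.integer(exon_sizes)
  total <- sum(exon_sizes)
  if (total %% 3L != 0L) abort("exon sizes must sum to a multiple of 3")
  if (total < 6L) abort("CDS must be at least 6 nt (start + stop)")
  n_codons <- total %/% 3L
  n_aa <- n_codons - 1L
  codons <- c("ATG",
              if (n_codons > 2L) sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
              "TAA")
  profile <- NULL
  if (n_aa >= 22L) {
    aa <- chars("HAEL")
    for (k in 1:4) codons[n_aa - 4L + k] <- codon_for(aa[k])
  }
  if (n_aa >= 463L + 18L) {
    profile <- diagnostic_column("gamma-PLE")
    full_pos <- as.integer(names(profile)) + 18L
    for (k in seq_along(full_pos)) codons[full_pos[k]] <- codon_for(profile[[k]])
  }
  cdna <- paste(codons, collapse = "")
  ends <- cumsum(exon_sizes)
  list(cdna = cdna,
       boundaries = tibble(exon = seq_along(exon_sizes),
                           start = ends - exon_sizes + 1L, end = ends),
       profile = profile)
}

#' Generate a synthetic gene cluster on one master locus
#'
#' Genes are laid out in `spec$gene_order`, separated by `intergenic_len` nt
#' of random spacer, with an optional random flank appended after the last
#' gene; every gene shares one reference CDS (recoded per isoform at the
#' diagnostic positions), emulating the high exon homology of the family.
#'
#' @inheritParams generate_gene
#' @param cdna_rec Advanced: a pre-generated reference CDS record (internal
#'   shape, as produced while generating another cluster) to share one base
#'   coding sequence across several loci; NULL generates a fresh one.
#' @return A list with `seq` (the master locus), `truth` (tibbles in locus
#'   coordinates) and `cdna`.
#' @export
generate_cluster <- function(spec, cdna_rec = NULL) {
  with_seed(spec$seed, {
    if (is.null(cdna_rec)) cdna_rec <- generate_cdna_unseeded(spec$exon_sizes)
    offset <- 0L
    pieces <- character(0)
    truths <- list()
    for (k in seq_along(spec$gene_order)) {
      g <- spec$gene_order[k]
      unit <- gene_unit(spec, g, cdna_rec)
      shift <- function(tb) {
        if (all(c("start", "end") %in% names(tb))) {
          tb$start <- tb$start + offset; tb$end <- tb$end + offset
        }
        tb
      }
      tr <- unit$truth
      tr$exons <- shift(tr$exons); tr$introns <- shift(tr$introns)
      tr$primer_sites <- shift(tr$primer_sites)
      tr$repeats <- tr$repeats |>
        mutate(across(c(copy1_start, copy1_end, copy2_start, copy2_end),
                      ~ .x + offset))
      tr$genes <- tr$genes |>
        mutate(across(c(unit_start, unit_end, body_start, body_end,
                        promoter_start, promoter_end), ~ .x + offset))
      truths[[g]] <- tr
      pieces <- c(pieces, unit$seq)
      offset <- offset + nchar(unit$seq)
      if (k < length(spec$gene_order)) {
        pieces <- c(pieces, random_dna(spec$intergenic_len))
        offset <- offset + spec$intergenic_len
      }
    }
    if (spec$flank_len > 0L) pieces <- c(pieces, random_dna(spec$flank_len))
    locus <- paste(pieces, collapse = "")
    truth <- list(
      genes = dplyr::bind_rows(lapply(truths, `[[`, "genes")),
      exons = dplyr::bind_rows(lapply(truths, `[[`, "exons")),
      introns = dplyr::bind_rows(lapply(truths, `[[`, "introns")),
      repeats = dplyr::bind_rows(lapply(truths, `[[`, "repeats")),
      primer_sites = dplyr::bind_rows(lapply(truths, `[[`, "primer_sites")),
      cds = do.call(c, lapply(truths, `[[`, "cds")),
      locus_len = nchar(locus)
    )
    list(seq = locus, truth = truth, cdna = cdna_rec$cdna,
         boundaries = cdna_rec$boundaries)
  })
}

#' Cut BAC clones out of a master locus
#'
#' Each clone is the cloning vector followed by the windowed insert, as in a
#' linearised BAC. The returned truth records per-clone offsets on the locus
#' and all pairwise window-intersection lengths.
#'
#' @param locus Master locus sequence (character).
#' @param windows A tibble/data.frame with columns `clone_id`, `start`,
#'   `end` (1-based inclusive locus coordinates; windows may overlap).
#' @param vector_seq Vector sequence prepended to every insert; defaults to
#'   the bundled synthetic pCC1BAC stand-in.
#' @return A list with `clones` (named character vector) and `truth`
#'   (list with `offsets` and `overlaps` tibbles).
#' @export
generate_bac_clones <- function(locus, windows, vector_seq = ple_vector()) {
  windows <- as_tibble(windows)
  n <- nchar(locus)
  if (any(windows$start < 1 | windows$end > n | windows$end < windows$start)) {
    abort("clone window outside the locus")
  }
  inserts <- substring(locus, windows$start, windows$end)
  clones <- stats::setNames(paste0(vector_seq, inserts), windows$clone_id)
  pairs <- if (nrow(windows) > 1) utils::combn(nrow(windows), 2) else
    matrix(integer(0), nrow = 2)
  overlaps <- tibble(
    cloneA = windows$clone_id[pairs[1, ]],
    cloneB = windows$clone_id[pairs[2, ]],
    length = pmax(0L, pmin(windows$end[pairs[1, ]], windows$end[pairs[2, ]]) -
                    pmax(windows$start[pairs[1, ]], windows$start[pairs[2, ]]) + 1L)
  )
  list(clones = clones,
       truth = list(offsets = windows |>
                      mutate(insert_len = end - start + 1L,
                             clone_len = insert_len + nchar(vector_seq)),
                    overlaps = overlaps))
}

# Does any bundled primer (or its reverse complement) occur in these
# sequences? Used to certify decoys as PCR-negative templates.
has_primer_site <- function(seqs, primers = ple_primers()) {
  set <- Biostrings::DNAStringSet(seqs)
  pats <- unique(c(primers$forward, primers$reverse,
                   revcomp(primers$forward), revcomp(primers$reverse)))
  hit <- rep(FALSE, length(seqs))
  for (p in pats) {
    hit <- hit | (Biostrings::vcountPattern(p, set) > 0)
  }
  hit
}

#' Generate a pooled BAC library with planted positives
#'
#' Builds the well-to-sequence map of a scaled 384-well-plate library:
#' positive wells (from `layout$positives`) carry the supplied positive
#' clone sequences; every other well carries a random decoy insert
#' certified to contain no screening-primer binding site.
#'
#' @param layout A [library_layout_spec()].
#' @param positive_clone_seqs Named character vector of clone sequences,
#'   keyed by the `gene_id` values used in `layout$positives`.
#' @param seed RNG seed.
#' @return A list with `wells` (tibble: `plate`, `row`, `col`, `well_id`,
#'   `gene_id`, `sequence`) and `truth` (tibble of planted positive wells).
#' @export
generate_library <- function(layout, positive_clone_seqs = character(0),
                             seed = DEFAULT_SEED) {
  pos <- layout$positives
  if (nrow(pos) > 0 && !all(pos$gene_id %in% names(positive_clone_seqs))) {
    abort("positive_clone_seqs must be named for every gene_id in the layout")
  }
  with_seed(seed, {
    grid <- expand.grid(col = seq_len(layout$cols), row = seq_len(layout$rows),
                        plate = seq_len(layout$n_plates)) |>
      as_tibble() |>
      select(plate, row, col)
    n <- nrow(grid)
    # decoys drawn as one block, then re-drawn well-wise until primer-free
    block <- sample(DNA_BASES, n * layout$decoy_insert_len, replace = TRUE)
    starts <- seq(1L, by = layout$decoy_insert_len, length.out = n)
    seqs <- vapply(starts, function(s) {
      paste(block[s:(s + layout$decoy_insert_len - 1L)], collapse = "")
    }, character(1))
    bad <- which(has_primer_site(seqs))
    while (length(bad) > 0) {
      seqs[bad] <- vapply(bad, function(i) random_dna(layout$decoy_insert_len),
                          character(1))
      bad <- bad[has_primer_site(seqs[bad])]
    }
    grid$well_id <- sprintf("P%03d-%s%02d", grid$plate,
                            LETTERS[grid$row], grid$col)
    grid$gene_id <- NA_character_
    grid$sequence <- seqs
    if (nrow(pos) > 0) {
      idx <- match(paste(pos$plate, pos$row, pos$col),
                   paste(grid$plate, grid$row, grid$col))
      grid$gene_id[idx] <- pos$gene_id
      grid$sequence[idx] <- unname(positive_clone_seqs[pos$gene_id])
    }
    list(wells = grid,
         truth = grid |> filter(!is.na(gene_id)) |>
           select(plate, row, col, well_id, gene_id))
  })
}

#' Simulate the five-clone BAC panel of the PLE locus
#'
#' Reproduces, with synthetic sequence, the published clone layout: one
#' three-gene cluster (PLE-G2, PLE-1, PLE-B9) covered by four overlapping
#' clones (BAC-10, BAC-206, BAC-70, BAC-75, the last running into a trailing
#' unknown region) and a second locus carrying PLE-C4 plus an unknown flank,
#' covered by BAC-119 alone. Flank lengths are scaled down from the tens of
#' kilobases of unknown sequence flanking the real clones.
#'
#' @param seed RNG seed.
#' @param point_mutation_rate Passed through to [cluster_spec()].
#' @return A list with `clones` (named character vector, vector + insert),
#'   `windows`, `loci` (the two master locus sequences), `truth` (per-locus
#'   cluster truth plus clone offsets) and `cdna`.
#' @export
generate_clone_panel <- function(seed = DEFAULT_SEED, point_mutation_rate = 0) {
  spec1 <- cluster_spec(gene_order = c("PLE-G2", "PLE-1", "PLE-B9"),
                        flank_len = 35000L, seed = seed,
                        point_mutation_rate = point_mutation_rate)
  spec2 <- cluster_spec(gene_order = "PLE-C4", flank_len = 40000L,
                        seed = seed + 1L,
                        point_mutation_rate = point_mutation_rate)
  # both loci share one base coding sequence, emulating the >= 96% exon
  # homology across the family
  base_cdna <- with_seed(seed, generate_cdna_unseeded(spec1$exon_sizes))
  sim1 <- generate_cluster(spec1, cdna_rec = base_cdna)
  sim2 <- generate_cluster(spec2, cdna_rec = base_cdna)
  len1 <- nchar(sim1$seq)
  len2 <- nchar(sim2$seq)
  w1 <- tibble(clone_id = c("BAC-10", "BAC-206", "BAC-70", "BAC-75"),
               start = c(1L, 600L, 95000L, 118000L),
               end = c(40000L, 102000L, 158000L, len1))
  w2 <- tibble(clone_id = "BAC-119", start = 1L, end = len2)
  cl1 <- generate_bac_clones(sim1$seq, w1)
  cl2 <- generate_bac_clones(sim2$seq, w2)
  list(clones = c(cl1$clones, cl2$clones),
       windows = list(cluster1 = w1, cluster2 = w2),
       loci = list(cluster1 = sim1$seq, cluster2 = sim2$seq),
       truth = list(cluster1 = sim1$truth, cluster2 = sim2$truth,
                    offsets = dplyr::bind_rows(cl1$truth$offsets,
                                               cl2$truth$offsets),
                    overlaps = cl1$truth$overlaps),
       cdna = sim1$cdna)
}

#' Write a named set of sequences as multi-FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
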