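#' Scoring and search parameters for cDNA-to-genomic spliced alignment
#'
#' The aligner is a two-state dynamic program: an exon state with
#' match/mismatch/gap moves and an intron state that can only be entered at a
#' genomic GT dinucleotide and left at an AG, at a flat (length-independent)
#' `intron_penalty`, with the intron length constrained to
#' `[min_intron, max_intron]`. `anchored` mode first locates candidate gene
#' regions by exact `anchor_k`-mer seeding and then runs the same DP inside
#' the seeded window; `full_dp` runs the DP over the whole input and serves
#' as the exact oracle.
#'
#' @param match,mismatch,gap Per-column scores (match > 0 > mismatch).
#' @param intron_penalty Flat score for opening one intron.
#' @param min_intron,max_intron Intron length bounds (nt); `min_intron >= 4`.
#' @param anchor_k Seed k-mer length for anchored mode.
#' @param mode `"anchored"` (default) or `"full_dp"`.
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap = -4L,
                         intron_penalty = -10L, min_intron = 40L,
                         max_intron = 20000L, anchor_k = 15L,
                         mode = c("anchored", "full_dp")) {
  mode <- match.arg(mode)
  if (match <= 0 || mismatch >= 0) abort("need match > 0 > mismatch")
  if (min_intron < 4) abort("min_intron must be >= 4")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap),
                 intron_penalty = as.integer(intron_penalty),
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 anchor_k = as.integer(anchor_k), mode = mode),
            class = "align_params")
}

new_gene_model <- function(contig_id, strand, exons, introns, cdna_id,
                           score, mismatch_count, gap_count, cds_sequence) {
  structure(list(contig_id = contig_id, strand = strand, exons = exons,
                 introns = introns, cdna_id = cdna_id, score = score,
                 mismatch_count = mismatch_count, gap_count = gap_count,
                 cds_sequence = cds_sequence),
            class = "gene_model")
}

empty_gene_model <- function(contig_id = NA_character_,
                             cdna_id = NA_character_) {
  new_gene_model(contig_id, NA_character_,
                 tibble(exon = integer(), start = integer(), end = integer()),
                 tibble(intron = integer(), start = integer(), end = integer()),
                 cdna_id, 0L, NA_integer_, NA_integer_, NA_character_)
}

#' @export
print.gene_model <- function(x, ...) {
  if (is_empty_model(x)) {
    cat("<gene_model: no gene found>\n")
    return(invisible(x))
  }
  cat(sprintf("<gene_model> %s [%s] %d..%d, %d exons / %d introns, score %d, %d mismatches\n",
              x$contig_id %||% "?", x$strand, min(x$exons$start),
              max(x$exons$end), nrow(x$exons), nrow(x$introns), x$score,
              x$mismatch_count))
  invisible(x)
}

#' Is a gene model empty (no gene found)?
#' @param model A `gene_model`.
#' @return TRUE if the model holds no exons.
#' @export
is_empty_model <- function(model) nrow(model$exons) == 0

#' @export
tidy.gene_model <- function(x, ...) {
  dplyr::bind_rows(
    x$exons |> mutate(feature = "exon", n = exon) |>
      select(feature, n, start, end),
    x$introns |> mutate(feature = "intron", n = intron) |>
      select(feature, n, start, end)
  ) |>
    arrange(start) |>
    mutate(contig_id = x$contig_id, strand = x$strand, width = end - start + 1L) |>
    select(contig_id, feature, n, start, end, width, strand)
}

#' @export
glance.gene_model <- function(x, ...) {
  tibble(contig_id = x$contig_id, strand = x$strand,
         n_exons = nrow(x$exons), n_introns = nrow(x$introns),
         span = if (is_empty_model(x)) NA_integer_ else
           max(x$exons$end) - min(x$exons$start) + 1L,
         score = x$score, mismatches = x$mismatch_count, gaps = x$gap_count)
}

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Candidate gene windows from exact k-mer seed hits, clustered by genomic
# position (split where consecutive seeds are more than max_intron apart).
seed_windows <- function(genomic, cdna, params, min_seeds = 3L) {
  k <- params$anchor_k
  n <- nchar(genomic)
  m <- nchar(cdna)
  if (m < k) return(tibble(start = 1L, end = n))
  ck <- unique(kmer_positions(cdna, k))
  gk <- kmer_positions(genomic, k)
  hit <- which(!is.na(match(gk, ck)))
  if (length(hit) < min_seeds) return(tibble(start = integer(), end = integer()))
  grp <- cumsum(c(1L, diff(hit) > params$max_intron))
  margin <- params$max_intron + m
  win <- tibble(g = grp, pos = hit) |>
    summarise(start = pmax(1L, min(pos) - margin),
              end = pmin(n, max(pos) + k - 1L + margin),
              n_seeds = dplyr::n(), .by = g) |>
    filter(n_seeds >= min_seeds) |>
    arrange(start)
  # merge overlapping windows
  if (nrow(win) > 1) {
    keep <- list()
    cur <- win[1, ]
    for (r in 2:nrow(win)) {
      if (win$start[r] <= cur$end) {
        cur$end <- max(cur$end, win$end[r])
      } else {
        keep[[length(keep) + 1L]] <- cur
        cur <- win[r, ]
      }
    }
    keep[[length(keep) + 1L]] <- cur
    win <- dplyr::bind_rows(keep)
  }
  win |> select(start, end)
}

run_dp <- function(genomic, cdna, params) {
  .spliced_dp(genomic, cdna, params$match, params$mismatch, params$gap,
              params$intron_penalty, params$min_intron, params$max_intron)
}

align_one_strand <- function(genomic, cdna, params) {
  windows <- if (params$mode == "full_dp") tibble(start = 1L, end = nchar(genomic))
             else seed_windows(genomic, cdna, params)
  # seedless small inputs fall back to the full matrix, so anchored mode is
  # exact on oracle-scale instances even when the cDNA is too short to seed
  if (nrow(windows) == 0 && nchar(genomic) <= 20000L) {
    windows <- tibble(start = 1L, end = nchar(genomic))
  }
  best <- NULL
  for (r in seq_len(nrow(windows))) {
    sub <- substr_strict(genomic, windows$start[r], windows$end[r])
    res <- run_dp(sub, cdna, params)
    res$offset <- windows$start[r] - 1L
    if (is.null(best) || res$score > best$score) best <- res
  }
  best
}

#' Spliced alignment of a cDNA onto genomic sequence
#'
#' Aligns the full cDNA against both strands of the genomic sequence under
#' the GT-AG rule and returns the maximum-score gene model. Every reported
#' intron starts with GT and ends with AG on the gene strand. If no
#' alignment scores above zero an empty model is returned (not an error).
#'
#' @param genomic Genomic sequence (character, A/C/G/T/N).
#' @param cdna Reference cDNA/CDS sequence (character).
#' @param params An [align_params()].
#' @param contig_id,cdna_id Identifiers carried into the model.
#' @return A `gene_model`: exon/intron intervals (1-based inclusive contig
#'   coordinates, sorted by position), strand, alignment score, mismatch and
#'   gap counts, and the spliced CDS sequence read off the gene strand.
#' @export
spliced_align <- function(genomic, cdna, params = align_params(),
                          contig_id = "contig", cdna_id = "cdna") {
  if (nchar(genomic) == 0 || nchar(cdna) == 0) abort("empty sequence")
  res_p <- align_one_strand(genomic, cdna, params)
  res_m <- align_one_strand(revcomp(genomic), cdna, params)
  use_minus <- !is.null(res_m) && (is.null(res_p) || res_m$score > res_p$score)
  res <- if (use_minus) res_m else res_p
  if (is.null(res) || res$score <= 0) {
    return(empty_gene_model(contig_id, cdna_id))
  }
  strand <- if (use_minus) "-" else "+"
  n <- nchar(genomic)
  gs <- res$exon_gstart + res$offset
  ge <- res$exon_gend + res$offset
  is_ <- res$intron_start + res$offset
  ie <- res$intron_end + res$offset
  if (use_minus) {
    tmp_s <- n - ge + 1L; tmp_e <- n - gs + 1L
    gs <- rev(tmp_s); ge <- rev(tmp_e)
    tmp_s <- n - ie + 1L; tmp_e <- n - is_ + 1L
    is_ <- rev(tmp_s); ie <- rev(tmp_e)
    exon_no <- rev(seq_along(gs))
    intron_no <- rev(seq_along(is_))
  } else {
    exon_no <- seq_along(gs)
    intron_no <- seq_along(is_)
  }
  exons <- tibble(exon = exon_no, start = gs, end = ge)
  introns <- tibble(intron = intron_no, start = is_, end = ie)
  cds <- paste(substring(genomic, gs, ge), collapse = "")
  if (use_minus) cds <- revcomp(cds)
  new_gene_model(contig_id, strand, exons, introns, cdna_id,
                 res$score, res$mismatches, res$gaps, cds)
}

#' Annotate all gene copies on a contig
#'
#' Repeatedly runs [spliced_align()], masking each found gene with N and
#' realigning, until the best remaining score drops below
#' `stop_fraction` of the first gene's score (or below zero). Models are
#' returned non-overlapping, sorted by contig position.
#'
#' @inheritParams spliced_align
#' @param stop_fraction Stop once the next best score falls below this
#'   fraction of the first model's score.
#' @param max_genes Safety cap on the number of reported models.
#' @return A list of `gene_model` objects (possibly empty).
#' @export
annotate_contig <- function(contig, cdna, params = align_params(),
                            contig_id = "contig", cdna_id = "cdna",
                            stop_fraction = 0.5, max_genes = 20L) {
  models <- list()
  masked <- contig
  first_score <- NULL
  repeat {
    model <- spliced_align(masked, cdna, params, contig_id, cdna_id)
    if (is_empty_model(model)) break
    if (is.null(first_score)) {
      first_score <- model$score
    } else if (model$score < stop_fraction * first_score) break
    models[[length(models) + 1L]] <- model
    span_start <- min(model$exons$start)
    span_end <- max(model$exons$end)
    substr(masked, span_start, span_end) <-
      paste(rep("N", span_end - span_start + 1L), collapse = "")
    if (length(models) >= max_genes) break
  }
  models[order(vapply(models, function(m) min(m$exons$start), integer(1)))]
}

#' Extract upstream, CDS and intron sequences for a gene model
#'
#' The upstream record is `upstream_len` nt 5' of exon 1 on the gene strand,
#' reported with promoter coordinates (+1 = A of the start codon, no
#' position 0). If the upstream region runs off the contig it is truncated
#' and flagged.
#'
#' @param model A non-empty `gene_model`.
#' @param contig The contig sequence the model was annotated on.
#' @param upstream_len Length of the upstream (regulatory) region to cut.
#' @return A tibble with one row per record (`upstream`, `cds`,
#'   `intron1`...): `region`, `sequence`, contig `start`/`end`, promoter
#'   coordinates for the upstream record, and a `truncated` flag.
#' @export
extract_regions <- function(model, contig, upstream_len = 6000L) {
  if (is_empty_model(model)) abort("cannot extract regions from an empty model")
  n <- nchar(contig)
  plus <- model$strand == "+"
  body_start <- min(model$exons$start)
  body_end <- max(model$exons$end)
  if (plus) {
    up_start <- max(1L, body_start - upstream_len)
    up_end <- body_start - 1L
    truncated <- (body_start - upstream_len) < 1L
    up_seq <- if (up_end >= up_start) substr(contig, up_start, up_end) else ""
  } else {
    up_start <- body_end + 1L
    up_end <- min(n, body_end + upstream_len)
    truncated <- (body_end + upstream_len) > n
    up_seq <- if (up_end >= up_start) revcomp(substr(contig, up_start, up_end)) else ""
  }
  got <- nchar(up_seq)
  rows <- list(
    tibble(region = "upstream", sequence = up_seq,
           start = up_start, end = up_end,
           promoter_start = if (got > 0) -got else NA_integer_,
           promoter_end = if (got > 0) -1L else NA_integer_,
           truncated = truncated),
    tibble(region = "cds", sequence = model$cds_sequence,
           start = body_start, end = body_end,
           promoter_start = NA_integer_, promoter_end = NA_integer_,
           truncated = FALSE)
  )
  if (nrow(model$introns) > 0) {
    intr <- model$introns |> arrange(intron)
    iseq <- substring(contig, intr$start, intr$end)
    if (!plus) iseq <- revcomp(iseq)
    rows[[3]] <- tibble(region = paste0("intron", intr$intron),
                        sequence = iseq, start = intr$start, end = intr$end,
                        promoter_start = NA_integer_,
                        promoter_end = NA_integer_, truncated = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment; identity is
#' matches / alignment columns x 100, reported to 0.1%.
#'
#' @param seqA,seqB Sequences (character).
#' @param alphabet `"nt"` or `"aa"`.
#' @return A one-row tibble: `identity`, `matches`, `columns`, `gaps`
#'   (number of gap columns).
#' @export
pairwise_identity <- function(seqA, seqB, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (nchar(seqA) == 0 || nchar(seqB) == 0) abort("empty sequence")
  if (alphabet == "nt") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
      substitutionMatrix = sm, gapOpening = 5, gapExtension = 2,
      type = "global")
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqA), Biostrings::AAString(seqB),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  pa <- chars(as.character(Biostrings::alignedPattern(aln)))
  ps <- chars(as.character(Biostrings::alignedSubject(aln)))
  columns <- length(pa)
  gaps <- sum(pa == "-" | ps == "-")
  matches <- sum(pa == ps & pa != "-")
  tibble(identity = round(100 * matches / columns, 1),
         matches = matches, columns = columns, gaps = gaps)
}

#' Summarise gene models in the printed-table layout
#'
#' One row per model with the gene span, strand, and per-exon / per-intron
#' sizes as `exon1`..`exonN`, `intron1`..`intronM` columns.
#'
#' @param models A list of `gene_model` objects.
#' @return A tibble.
#' @export
model_summary <- function(models) {
  purrr::imap(models, function(m, k) {
    ex <- m$exons |> arrange(exon)
    it <- m$introns |> arrange(intron)
    row <- tibble(model = k, contig_id = m$contig_id, strand = m$strand,
                  span = max(ex$end) - min(ex$start) + 1L,
                  score = m$score, mismatches = m$mismatch_count)
    for (r in seq_len(nrow(ex))) {
      row[[paste0("exon", ex$exon[r])]] <- ex$end[r] - ex$start[r] + 1L
    }
    for (r in seq_len(nrow(it))) {
      row[[paste0("intron", it$intron[r])]] <- it$end[r] - it$start[r] + 1L
    }
    row
  }) |> dplyr::bind_rows()
}
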