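# GFF3 serialisation of gene models, via rtracklayer/GenomicRanges.
# Features are written 1-based inclusive as gene -> mRNA -> exon/CDS, with
# the alignment score, mismatch count and cDNA id kept as attributes of the
# gene feature.

models_to_granges <- function(models) {
  rows <- purrr::imap(models, function(m, k) {
    gid <- sprintf("gene%d", k)
    mid <- sprintf("mRNA%d", k)
    ex <- m$exons |> arrange(start)
    body_start <- min(ex$start)
    body_end <- max(ex$end)
    dplyr::bind_rows(
      tibble(seqid = m$contig_id, type = "gene", start = body_start,
             end = body_end, strand = m$strand, ID = gid, Parent = NA_character_,
             cdna_id = m$cdna_id, alignment_score = m$score,
             mismatch_count = m$mismatch_count),
      tibble(seqid = m$contig_id, type = "mRNA", start = body_start,
             end = body_end, strand = m$strand, ID = mid, Parent = gid,
             cdna_id = NA_character_, alignment_score = NA_integer_,
             mismatch_count = NA_integer_),
      tibble(seqid = m$contig_id, type = "exon", start = ex$start,
             end = ex$end, strand = m$strand,
             ID = sprintf("%s.exon%d", mid, ex$exon), Parent = mid,
             cdna_id = NA_character_, alignment_score = NA_integer_,
             mismatch_count = NA_integer_),
      {
        # CDS phase: bases of the preceding parts, in translation order
        widths <- ex$end - ex$start + 1L
        ord <- order(ex$exon)  # translation order (reversed on "-")
        prior <- integer(nrow(ex))
        prior[ord] <- cumsum(c(0L, widths[ord][-nrow(ex)]))
        tibble(seqid = m$contig_id, type = "CDS", start = ex$start,
               end = ex$end, strand = m$strand,
               ID = sprintf("%s.cds", mid), Parent = mid,
               cdna_id = NA_character_, alignment_score = NA_integer_,
               mismatch_count = NA_integer_,
               phase = (3L - prior %% 3L) %% 3L)
      }
    )
  })
  tb <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tb$seqid,
    ranges = IRanges::IRanges(start = tb$start, end = tb$end),
    strand = tb$strand)
  S4Vectors::mcols(gr)$type <- tb$type
  S4Vectors::mcols(gr)$ID <- tb$ID
  S4Vectors::mcols(gr)$Parent <- tb$Parent
  S4Vectors::mcols(gr)$cdna_id <- tb$cdna_id
  S4Vectors::mcols(gr)$alignment_score <- tb$alignment_score
  S4Vectors::mcols(gr)$mismatch_count <- tb$mismatch_count
  S4Vectors::mcols(gr)$phase <- tb$phase
  gr
}

#' Write gene models to a GFF3 file
#'
#' @param models List of `gene_model` objects (may be empty).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (length(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- models_to_granges(models)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models back from a GFF3 file
#'
#' Inverse of [write_gff3()]. If `contig` is supplied the spliced CDS
#' sequence of each model is reconstructed from it, completing the round
#' trip.
#'
#' @param path GFF3 file written by [write_gff3()] (or compatible).
#' @param contig Optional contig sequence (character) to refill
#'   `cds_sequence`.
#' @return A list of `gene_model` objects sorted by position.
#' @export
read_gff3 <- function(path, contig = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(sprintf("malformed GFF3 '%s': %s", path,
                                 conditionMessage(e)))
                 })
  if (length(gr) == 0) return(list())
  mc <- S4Vectors::mcols(gr)
  opt_col <- function(nm, as_fun, default) {
    if (nm %in% names(mc)) suppressWarnings(as_fun(mc[[nm]])) else
      rep(default, length(gr))
  }
  tb <- tibble(seqid = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               type = as.character(mc$type),
               ID = as.character(mc$ID),
               Parent = vapply(as.list(mc$Parent), function(p) {
                 if (length(p) == 0) NA_character_ else as.character(p[[1]])
               }, character(1)),
               cdna_id = opt_col("cdna_id", as.character, NA_character_),
               alignment_score = opt_col("alignment_score", as.integer,
                                         NA_integer_),
               mismatch_count = opt_col("mismatch_count", as.integer,
                                        NA_integer_))
  genes <- tb |> filter(type == "gene")
  models <- purrr::map(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    mrna <- tb |> filter(type == "mRNA", Parent == g$ID)
    ex <- tb |> filter(type == "exon", Parent %in% mrna$ID) |> arrange(start)
    minus <- g$strand == "-"
    n_ex <- nrow(ex)
    exons <- tibble(exon = if (minus) rev(seq_len(n_ex)) else seq_len(n_ex),
                    start = ex$start, end = ex$end)
    introns <- if (n_ex > 1) {
      tibble(intron = if (minus) rev(seq_len(n_ex - 1L)) else seq_len(n_ex - 1L),
             start = ex$end[-n_ex] + 1L, end = ex$start[-1] - 1L)
    } else {
      tibble(intron = integer(), start = integer(), end = integer())
    }
    cds <- NA_character_
    if (!is.null(contig)) {
      cds <- paste(substring(contig, exons$start, exons$end), collapse = "")
      if (minus) cds <- revcomp(cds)
    }
    new_gene_model(g$seqid, g$strand, exons, introns, g$cdna_id,
                   g$alignment_score, g$mismatch_count, NA_integer_, cds)
  })
  models[order(vapply(models, function(m) min(m$exons$start), integer(1)))]
}

#' Convert generator ground truth to gene models
#'
#' Lets the planted truth of a synthetic cluster be written with
#' [write_gff3()] and compared feature-by-feature with annotation output.
#'
#' @param truth Truth list from [generate_cluster()] or [generate_gene()].
#' @param contig Optional locus sequence to fill `cds_sequence`.
#' @param contig_id,cdna_id Identifiers to stamp on the models.
#' @return A list of `gene_model` objects in gene order.
#' @export
truth_models <- function(truth, contig = NULL, contig_id = "contig",
                         cdna_id = "cdna") {
  purrr::map(seq_len(nrow(truth$genes)), function(k) {
    g <- truth$genes[k, ]
    ex <- truth$exons |> filter(gene_id == g$gene_id) |> arrange(start)
    it <- truth$introns |> filter(gene_id == g$gene_id) |> arrange(start)
    minus <- g$strand == "-"
    exons <- tibble(exon = if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex)),
                    start = ex$start, end = ex$end)
    introns <- tibble(intron = if (minus) rev(seq_len(nrow(it))) else seq_len(nrow(it)),
                      start = it$start, end = it$end)
    cds <- NA_character_
    if (!is.null(contig)) {
      cds <- paste(substring(contig, exons$start, exons$end), collapse = "")
      if (minus) cds <- revcomp(cds)
    }
    new_gene_model(contig_id, g$strand, exons, introns, cdna_id,
                   NA_integer_, 0L, 0L, cds)
  })
}

#' Write generator ground truth as GFF3 plus a JSON sidecar
#'
#' The GFF3 carries the gene/exon structure; the JSON sidecar carries the
#' planted repeat pairs, primer sites and (when present) clone offsets and
#' overlaps, which have no natural GFF3 representation.
#'
#' @param truth Truth list from the generators.
#' @param gff_path,json_path Output paths.
#' @param contig_id Contig name to write.
#' @return Invisibly, a list of the two paths.
#' @export
write_ground_truth <- function(truth, gff_path, json_path,
                               contig_id = "locus") {
  write_gff3(truth_models(truth, contig_id = contig_id), gff_path)
  side <- truth[setdiff(names(truth), c("genes", "exons", "introns", "cds"))]
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(gff = gff_path, json = json_path))
}
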