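#' Parameterisation of a planted promoter repeat pair
#'
#' Describes the pair of reverse-complement (inverted) 720-nt copies planted
#' in every synthetic promoter. Coordinates use the promoter convention:
#' +1 is the A of the start codon, -1 the base immediately upstream, and
#' there is no position 0. Each `copyN_start` is the most-upstream (most
#' negative) coordinate of that copy, so the defaults place copy 1 at
#' (-5132..-4413) and copy 2 at (-802..-83).
#'
#' @param length Repeat length in nt.
#' @param copy1_start,copy2_start Promoter coordinate of the first base of
#'   each copy.
#' @param max_mismatches Maximum number of mismatches introduced between the
#'   two copies (0 = exact reverse complements).
#' @return An object of class `repeat_plant_spec`.
#' @export
repeat_plant_spec <- function(length = 720L, copy1_start = -5132L,
                              copy2_start = -802L, max_mismatches = 0L) {
  length <- as.integer(length)
  copy1_start <- as.integer(copy1_start)
  copy2_start <- as.integer(copy2_start)
  if (length < 1) abort("repeat length must be >= 1")
  if (copy1_start >= 0 || copy2_start >= 0) {
    abort("repeat copies must lie upstream of the start codon (negative coordinates)")
  }
  c1_end <- copy1_start + length - 1L
  c2_end <- copy2_start + length - 1L
  if (c1_end >= copy2_start) abort("repeat copies must not overlap")
  structure(list(length = length, copy1_start = copy1_start,
                 copy2_start = copy2_start,
                 max_mismatches = as.integer(max_mismatches)),
            class = "repeat_plant_spec")
}

#' Parameterisation of a synthetic PLE-like gene cluster
#'
#' Collects everything the generator needs to emit a gene cluster with known
#' ground truth: per-gene exon and intron sizes (defaulting to the bundled
#' printed tables), the intergenic spacer length (~22 kb in the real
#' cluster), the promoter length, the planted inverted-repeat pair, the gene
#' order deduced for chromosome 6, per-gene strands, and a per-base point
#' mutation rate applied to each gene copy.
#'
#' @param gene_order Character vector of gene ids in cluster order. Each id
#'   must have a row in the bundled intron table (or `intron_sizes` must be
#'   supplied) and, for diagnostic-residue planting, a column in
#'   [ple_diagnostics()].
#' @param exon_sizes Integer vector of exon sizes (nt), one per exon; shared
#'   by all genes in the cluster as in the printed table.
#' @param intron_sizes Named list of 13-length integer vectors, one per gene
#'   id; defaults to the bundled per-gene table rows.
#' @param intergenic_len Intergenic spacer length (nt).
#' @param promoter_len Promoter (regulatory region) length (nt).
#' @param repeat_plant A [repeat_plant_spec()].
#' @param gene_strands Named character vector of "+"/"-" per gene id;
#'   defaults to all "+".
#' @param point_mutation_rate Per-base substitution probability in [0, 0.05]
#'   applied per gene copy; never touches splice dinucleotides, start/stop
#'   codons, diagnostic codons or planted primer sites.
#' @param flank_len Random sequence appended after the last gene (nt), used
#'   to emulate trailing unknown-gene regions.
#' @param plant_primers Integer ids of bundled screening primer pairs whose
#'   amplicon cassettes are planted in the first introns of every gene
#'   (default pairs 1 and 2, the single-product screening pairs).
#' @param seed RNG seed; identical spec and seed give byte-identical output.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(gene_order = c("PLE-G2", "PLE-1", "PLE-B9"),
                         exon_sizes = exon_sizes_for("gamma-PLE"),
                         intron_sizes = NULL,
                         intergenic_len = 22000L,
                         promoter_len = 6000L,
                         repeat_plant = repeat_plant_spec(),
                         gene_strands = NULL,
                         point_mutation_rate = 0,
                         flank_len = 0L,
                         plant_primers = c(1L, 2L),
                         seed = DEFAULT_SEED) {
  exon_sizes <- as.integer(exon_sizes)
  if (length(gene_order) < 1) abort("gene_order must name at least one gene")
  if (any(exon_sizes < 1)) abort("all exon sizes must be >= 1")
  if (is.null(intron_sizes)) {
    intron_sizes <- lapply(stats::setNames(gene_order, gene_order),
                           intron_sizes_for)
  }
  if (!all(gene_order %in% names(intron_sizes))) {
    abort("intron_sizes must contain an entry for every gene in gene_order")
  }
  intron_sizes <- lapply(intron_sizes, as.integer)
  for (g in gene_order) {
    if (length(exon_sizes) != length(intron_sizes[[g]]) + 1L) {
      abort(sprintf("gene '%s': number of exons must equal number of introns + 1", g))
    }
    if (any(intron_sizes[[g]] < 4L)) {
      abort(sprintf("gene '%s': intron sizes must be >= 4 to hold GT...AG", g))
    }
  }
  if (point_mutation_rate < 0 || point_mutation_rate > 0.05) {
    abort("point_mutation_rate must be in [0, 0.05]")
  }
  if (is.null(gene_strands)) {
    gene_strands <- stats::setNames(rep("+", length(gene_order)), gene_order)
  }
  if (!all(gene_order %in% names(gene_strands)) ||
      !all(gene_strands %in% c("+", "-"))) {
    abort("gene_strands must map every gene id to '+' or '-'")
  }
  if (!inherits(repeat_plant, "repeat_plant_spec")) {
    abort("repeat_plant must be a repeat_plant_spec()")
  }
  if (-repeat_plant$copy1_start > promoter_len) {
    abort("planted repeat copy 1 lies outside the promoter")
  }
  structure(list(gene_order = gene_order,
                 exon_sizes = exon_sizes,
                 intron_sizes = intron_sizes,
                 intergenic_len = as.integer(intergenic_len),
                 promoter_len = as.integer(promoter_len),
                 repeat_plant = repeat_plant,
                 gene_strands = gene_strands,
                 point_mutation_rate = point_mutation_rate,
                 flank_len = as.integer(flank_len),
                 plant_primers = as.integer(plant_primers),
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Layout of a pooled 384-well BAC library
#'
#' The real library holds 192,000 clones as 500 plates of 16 rows x 24
#' columns; simulations scale the plate count down while keeping the plate
#' geometry. `positives` assigns gene-carrying clones to wells; all other
#' wells receive random decoy inserts guaranteed to carry no screening
#' primer sites.
#'
#' @param n_plates Number of 384-well plates.
#' @param rows,cols Plate geometry (16 x 24 by default).
#' @param positives A tibble/data.frame with columns `plate`, `row`, `col`,
#'   `gene_id`, or NULL for a decoy-only library.
#' @param decoy_insert_len Length (nt) of the random decoy insert placed in
#'   non-positive wells.
#' @return An object of class `library_layout_spec`.
#' @export
library_layout_spec <- function(n_plates, rows = 16L, cols = 24L,
                                positives = NULL, decoy_insert_len = 2000L) {
  n_plates <- as.integer(n_plates)
  if (n_plates < 1) abort("n_plates must be >= 1")
  if (!is.null(positives)) {
    positives <- as_tibble(positives)
    need <- c("plate", "row", "col", "gene_id")
    if (!all(need %in% names(positives))) {
      abort("positives needs columns plate, row, col, gene_id")
    }
    if (any(positives$plate < 1 | positives$plate > n_plates |
            positives$row < 1 | positives$row > rows |
            positives$col < 1 | positives$col > cols)) {
      abort("positive well outside the library layout")
    }
    key <- paste(positives$plate, positives$row, positives$col)
    if (anyDuplicated(key)) abort("duplicate positive well assignment")
  } else {
    positives <- tibble(plate = integer(), row = integer(), col = integer(),
                        gene_id = character())
  }
  structure(list(n_plates = n_plates, rows = as.integer(rows),
                 cols = as.integer(cols), positives = positives,
                 decoy_insert_len = as.integer(decoy_insert_len)),
            class = "library_layout_spec")
}
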