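#' Bundled reference tables for the PLE gene family
#'
#' The package bundles, as plain TSV fixtures, the printed reference values
#' that parameterise the synthetic-data generator and the isoenzyme
#' classifier: per-gene exon sizes (identical across the four genes),
#' per-gene intron sizes, the 25 diagnostic amino-acid positions across the
#' eleven known isoenzymes (mature-peptide numbering, i.e. after removal of
#' the 18-residue signal peptide), and the eight-primer screening panel with
#' annealing temperatures and expected product sizes.
#'
#' @return Each loader returns a tibble:
#' \describe{
#'   \item{ple_exon_sizes()}{one row per gene, columns `exon1`..`exon14` plus
#'     `aa_homology` (percent amino-acid identity to \eqn{\gamma}-PLE).}
#'   \item{ple_intron_sizes()}{one row per gene copy, columns
#'     `intron1`..`intron13`.}
#'   \item{ple_diagnostics()}{25 rows, one column per isoenzyme, `position`
#'     in mature-peptide numbering.}
#'   \item{ple_primers()}{one row per primer pair with `forward`, `reverse`,
#'     `annealing_temp` and `expected_products` (list column of numeric
#'     product sizes).}
#' }
#' @name ple_tables
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "plegenes")
  if (path == "") abort(sprintf("bundled fixture '%s' not found", file))
  path
}

read_fixture <- function(file, col_types) {
  readr::read_tsv(extdata(file), col_types = col_types, progress = FALSE)
}

#' @rdname ple_tables
#' @export
ple_exon_sizes <- function() {
  read_fixture("exon_sizes.tsv", readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname ple_tables
#' @export
ple_intron_sizes <- function() {
  read_fixture("intron_sizes.tsv", readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname ple_tables
#' @export
ple_diagnostics <- function() {
  read_fixture("diagnostic_positions.tsv", readr::cols(
    position = readr::col_integer(), .default = readr::col_character()
  ))
}

#' @rdname ple_tables
#' @export
ple_primers <- function() {
  tbl <- read_fixture("screening_primers.tsv", readr::cols(
    id = readr::col_integer(),
    forward = readr::col_character(),
    reverse = readr::col_character(),
    annealing_temp = readr::col_double(),
    products = readr::col_character()
  ))
  tbl$expected_products <- lapply(strsplit(tbl$products, "/", fixed = TRUE),
                                  as.numeric)
  tbl$products <- NULL
  tbl
}

#' Exon or intron sizes for one gene
#'
#' Convenience accessors over [ple_exon_sizes()] / [ple_intron_sizes()].
#' `gene` is matched against the table's `gene` column; for introns,
#' `"PLE-B9"` resolves to the BAC-70 copy.
#'
#' @param gene Gene identifier, e.g. `"PLE-1"`.
#' @return An integer vector of 14 exon sizes or 13 intron sizes (nt).
#' @export
exon_sizes_for <- function(gene = "gamma-PLE") {
  tbl <- ple_exon_sizes()
  row <- tbl[tbl$gene == gene, ]
  if (nrow(row) == 0) abort(sprintf("unknown gene '%s'", gene))
  as.integer(row[1, paste0("exon", 1:14)])
}

#' @rdname exon_sizes_for
#' @export
intron_sizes_for <- function(gene = "PLE-1") {
  tbl <- ple_intron_sizes()
  key <- if (gene == "PLE-B9") "PLE-B9(70)" else gene
  row <- tbl[tbl$gene == key, ]
  if (nrow(row) == 0) abort(sprintf("unknown gene '%s'", gene))
  as.integer(row[1, paste0("intron", 1:13)])
}

#' Diagnostic residue profile of a reference isoenzyme
#'
#' @param name Column name in [ple_diagnostics()], e.g. `"gamma-PLE"`.
#' @return A named character vector: names are the 25 mature-peptide
#'   positions, values one-letter residues.
#' @export
diagnostic_column <- function(name) {
  tbl <- ple_diagnostics()
  if (!name %in% names(tbl)) abort(sprintf("unknown isoenzyme '%s'", name))
  stats::setNames(tbl[[name]], tbl$position)
}

#' Synthetic stand-in for the pCC1BAC cloning vector
#'
#' An 8128-nt fixed-seed random sequence bundled as FASTA, used wherever the
#' cloning vector is needed (clone simulation, vector trimming). It is a
#' synthetic stand-in, not the true pCC1BAC sequence; users working with real
#' clones should supply the real vector instead.
#'
#' @return A single character string of length 8128.
#' @export
ple_vector <- function() {
  as.character(Biostrings::readDNAStringSet(extdata("pCC1BAC_synthetic.fasta"))[[1]])
}
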