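# Isoenzyme-level analysis: CDS translation, protein features (signal
# peptide, ER-retention signal) and classification by the 25 diagnostic
# amino-acid positions that distinguish the known PLE isoenzymes. Diagnostic
# positions use mature-peptide numbering: the 18-residue signal peptide is
# removed before counting.

SIGNAL_PEPTIDE_LEN <- 18L

#' Translate a CDS and extract protein features
#'
#' Standard-genetic-code translation of a coding sequence; the terminal stop
#' is excluded from the protein. Extracted features are positional: the
#' signal peptide is defined as residues 1-18, the ER-retention signal as
#' the C-terminal tetrapeptide (HAEL in PLE), and `third_from_bottom` is the
#' third residue from the C terminus (a species-diagnostic position in
#' carboxylesterase retention signals).
#'
#' @param cds Coding sequence (character); must be a multiple of 3, start
#'   with ATG (warned otherwise) and contain a single terminal stop.
#' @return A one-row tibble: `protein`, `length`, `signal_peptide`,
#'   `c_terminal_4`, `third_from_bottom`, `atg_start`.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length is not a multiple of 3")
  if (n < 6L) abort("CDS must contain at least a start and a stop codon")
  aa_full <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                if.fuzzy.codon = "solve"))
  aa_v <- chars(aa_full)
  n_aa <- length(aa_v)
  internal_stops <- which(aa_v[-n_aa] == "*")
  if (length(internal_stops) > 0) {
    abort(sprintf("internal stop codon at codon %d", internal_stops[1]))
  }
  if (aa_v[n_aa] != "*") abort("CDS does not end with a stop codon")
  atg_start <- substr(cds, 1, 3) == "ATG"
  if (!atg_start) warn("CDS does not start with ATG")
  protein <- substr(aa_full, 1, n_aa - 1L)
  len <- n_aa - 1L
  tibble(protein = protein, length = len,
         signal_peptide = if (len >= SIGNAL_PEPTIDE_LEN)
           substr(protein, 1, SIGNAL_PEPTIDE_LEN) else NA_character_,
         c_terminal_4 = if (len >= 4) substr(protein, len - 3L, len)
           else NA_character_,
         third_from_bottom = if (len >= 3)
           substr(protein, len - 2L, len - 2L) else NA_character_,
         atg_start = atg_start)
}

#' Read the diagnostic residues of a protein
#'
#' Strips the 18-residue signal peptide and reads the 25 diagnostic
#' positions in mature-peptide numbering.
#'
#' @param protein Protein sequence (character, no stop).
#' @param positions Diagnostic positions (mature numbering); defaults to the
#'   bundled set.
#' @return A tibble with `position` and `residue` (one row per position).
#' @export
diagnostic_profile <- function(protein, positions = ple_diagnostics()$position) {
  need <- max(positions) + SIGNAL_PEPTIDE_LEN
  if (nchar(protein) < need) {
    abort(sprintf("protein too short: need >= %d aa, got %d", need,
                  nchar(protein)))
  }
  mature <- substr(protein, SIGNAL_PEPTIDE_LEN + 1L, nchar(protein))
  tibble(position = as.integer(positions),
         residue = substring(mature, positions, positions))
}

profile_vector <- function(profile) {
  if (is.data.frame(profile)) {
    stats::setNames(profile$residue, profile$position)
  } else {
    profile
  }
}

#' Number of diagnostic-position differences between two profiles
#'
#' A metric over profiles: symmetric, zero iff equal. Ambiguous residues
#' ("X") always count as mismatches.
#'
#' @param a,b Profiles (tibbles from [diagnostic_profile()] or named
#'   character vectors keyed by position).
#' @return Integer mismatch count.
#' @export
profile_mismatches <- function(a, b) {
  va <- profile_vector(a); vb <- profile_vector(b)
  pos <- names(va)
  if (!setequal(pos, names(vb))) abort("profiles cover different positions")
  vb <- vb[pos]
  sum(va != vb | va == "X" | vb == "X")
}

#' Classify an isoform by its diagnostic profile
#'
#' Compares a profile against the reference isoenzyme columns and returns
#' the best match; a profile matching no reference exactly is declared
#' novel.
#'
#' @param profile Tibble from [diagnostic_profile()] or named vector.
#' @param references Reference table in the shape of [ple_diagnostics()].
#' @return A list of class `isoform_call`: `best` (reference name),
#'   `best_mismatches`, `novel` (TRUE if the minimum mismatch count is > 0)
#'   and `mismatch_table` (tibble over all references, ascending).
#' @export
classify_isoform <- function(profile, references = ple_diagnostics()) {
  va <- profile_vector(profile)
  refs <- setdiff(names(references), "position")
  mm <- vapply(refs, function(r) {
    profile_mismatches(va, stats::setNames(references[[r]],
                                           references$position))
  }, integer(1))
  # stable sort: ties keep the reference table's column order, so a profile
  # identical to two references (PLE-1 is identical to gamma-PLE) reports
  # the earlier, canonical column
  tbl <- tibble(reference = refs, mismatches = unname(mm)) |>
    arrange(mismatches)
  structure(list(best = tbl$reference[1],
                 best_mismatches = tbl$mismatches[1],
                 novel = tbl$mismatches[1] > 0L,
                 mismatch_table = tbl),
            class = "isoform_call")
}

#' @export
print.isoform_call <- function(x, ...) {
  cat(sprintf("<isoform_call> best match: %s (%d mismatches)%s\n", x$best,
              x$best_mismatches, if (x$novel) " -- novel isoform" else ""))
  invisible(x)
}

#' @export
tidy.isoform_call <- function(x, ...) x$mismatch_table

#' @export
glance.isoform_call <- function(x, ...) {
  tibble(best = x$best, best_mismatches = x$best_mismatches, novel = x$novel)
}

#' Pairwise percent-identity matrix for a set of proteins
#'
#' Global-alignment percent identity (via [pairwise_identity()]) for every
#' pair; the matrix is symmetric with 100 on the diagonal.
#'
#' @param proteins Named character vector of protein sequences.
#' @return A numeric matrix with dimnames from `proteins`.
#' @export
identity_matrix <- function(proteins) {
  if (length(proteins) < 2) abort("need at least two proteins")
  n <- length(proteins)
  ids <- names(proteins) %||% as.character(seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- pairwise_identity(proteins[[i]], proteins[[j]], "aa")$identity
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}

#' Count positions at which reference isoenzymes differ
#'
#' The number of diagnostic rows at which the given reference columns are
#' not all identical.
#'
#' @param references Table shaped like [ple_diagnostics()].
#' @return Integer count.
#' @export
variable_position_count <- function(references = ple_diagnostics()) {
  refs <- setdiff(names(references), "position")
  sum(apply(as.matrix(references[, refs]), 1,
            function(row) length(unique(row)) > 1))
}
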