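#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap keep discard
#' @importFrom generics tidy glance
#' @useDynLib plegenes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' @export
generics::tidy

#' @export
generics::glance

DNA_BASES <- c("A", "C", "G", "T")

# Default RNG seed used by the generators when none is supplied.
DEFAULT_SEED <- 1063L

#' Reverse complement of a DNA string
#'
#' @param x A character vector of DNA sequences (A/C/G/T/N).
#' @return A character vector of the same length with each sequence
#'   reverse-complemented.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. uniformly from A/C/G/T. Callers that need
#' reproducibility should wrap the call in [with_seed()].
#'
#' @param n Sequence length in nucleotides.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so
#' that generator calls are reproducible without disturbing the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# substr() that errors on out-of-range coordinates instead of silently
# truncating.
substr_strict <- function(x, start, end) {
  n <- nchar(x)
  if (start < 1 || end > n || end < start) {
    abort(sprintf("substring [%d, %d] out of range for sequence of length %d",
                  start, end, n))
  }
  substr(x, start, end)
}

# Convert a promoter coordinate (+1 = A of ATG, no position 0) to a 1-based
# index into a promoter string of length `promoter_len` that ends at -1.
promoter_index <- function(pos, promoter_len) {
  stopifnot(all(pos != 0))
  idx <- ifelse(pos < 0, pos + promoter_len + 1L, NA_integer_)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > promoter_len)) {
    abort("promoter coordinate outside [-promoter_len, -1]")
  }
  as.integer(idx)
}

# Inverse of promoter_index().
promoter_coord <- function(idx, promoter_len) {
  as.integer(idx) - promoter_len - 1L
}
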