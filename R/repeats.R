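# Inverted-repeat (reverse-complement pair) detection in promoter sequence.
# A pair is two non-overlapping segments where the downstream copy is the
# reverse complement of the upstream copy; such pairs can base-pair into a
# stem-loop, which is why the planted 720-nt pair in the PLE promoters is of
# regulatory interest.

new_repeat_pair_tbl <- function() {
  tibble(copy1_start = integer(), copy1_end = integer(),
         copy2_start = integer(), copy2_end = integer(),
         length = integer(), mismatches = integer(), separation = integer())
}

# Convert a run in (S x revcomp(S)) match space to pair coordinates on S.
# A run on diagonal d covers S positions a..b on the first arm and, through
# the reverse complement, S positions (n-(b-d)+1)..(n-(a-d)+1) on the second.
run_to_pair <- function(a, b, d, n, mismatches, offset) {
  c1s <- a; c1e <- b
  c2s <- n - (b - d) + 1L
  c2e <- n - (a - d) + 1L
  tibble(copy1_start = c1s + offset, copy1_end = c1e + offset,
         copy2_start = c2s + offset, copy2_end = c2e + offset,
         length = c1e - c1s + 1L, mismatches = mismatches,
         separation = c2s - c1e)
}

# Trim a palindromic run (arms overlapping) to the longest prefix whose two
# arms do not overlap; returns NULL if nothing is left.
trim_self_overlap <- function(a, b, d, n) {
  # arms overlap iff copy1_end >= copy2_start, i.e. b >= n - (b - d) + 1
  bmax <- floor((n + d) / 2)
  if (b <= bmax) return(c(a, b))
  if (bmax < a) return(NULL)
  c(a, as.integer(bmax))
}

canonicalise_pairs <- function(tb) {
  if (nrow(tb) == 0) return(new_repeat_pair_tbl())
  tb <- tb |>
    filter(copy1_end < copy2_start) |>
    filter(copy1_start <= copy2_start) |>  # report each pair once
    distinct(copy1_start, copy1_end, copy2_start, copy2_end, .keep_all = TRUE)
  if (nrow(tb) == 0) return(new_repeat_pair_tbl())
  # drop pairs contained in a longer pair
  keep <- rep(TRUE, nrow(tb))
  ord <- order(-tb$length)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    for (jj in seq_along(ord)) {
      j <- ord[jj]
      if (i == j || !keep[j] || tb$length[j] > tb$length[i]) next
      if (tb$length[j] < tb$length[i] &&
          tb$copy1_start[j] >= tb$copy1_start[i] &&
          tb$copy1_end[j] <= tb$copy1_end[i] &&
          tb$copy2_start[j] >= tb$copy2_start[i] &&
          tb$copy2_end[j] <= tb$copy2_end[i]) {
        keep[j] <- FALSE
      }
    }
  }
  tb[keep, ] |> arrange(desc(length), copy1_start)
}

# Maximal exact runs around seed hits on one diagonal of the
# S x revcomp(S) match space.
exact_runs_from_seeds <- function(sv, rv, hits, d) {
  n <- length(sv)
  lo <- max(1L, 1L + d)
  hi <- min(n, n + d)
  runs <- list()
  claimed_to <- lo - 1L
  for (h in sort(hits)) {
    if (h <= claimed_to) next
    a <- h; b <- h
    while (b + 1L <= hi && sv[b + 1L] == rv[b + 1L - d]) b <- b + 1L
    while (a - 1L >= lo && sv[a - 1L] == rv[a - 1L - d]) a <- a - 1L
    runs[[length(runs) + 1L]] <- c(a, b)
    claimed_to <- b + 1L  # a mismatch separates this run from the next
  }
  runs
}

# Chain exact runs (already sorted, each of length >= min_run) along one
# diagonal: gaps between chained runs count as mismatches, and the total
# must stay within floor(rate x chained span). Emits the greedy rightward
# chain from every start; contained chains are discarded later.
chain_runs <- function(runs, rate) {
  if (length(runs) == 0) return(list())
  a <- vapply(runs, `[`, integer(1), 1L)
  b <- vapply(runs, `[`, integer(1), 2L)
  out <- list()
  for (i in seq_along(runs)) {
    j <- i
    mm <- 0L
    while (j + 1L <= length(runs)) {
      gap <- a[j + 1L] - b[j] - 1L
      span <- b[j + 1L] - a[i] + 1L
      if (mm + gap <= floor(rate * span)) {
        mm <- mm + gap
        j <- j + 1L
      } else break
    }
    out[[length(out) + 1L]] <- c(a[i], b[j], mm)
  }
  out
}

#' Find inverted (reverse-complement) repeat pairs
#'
#' Seed-and-extend search of a sequence against its own reverse complement:
#' exact 20-mer seeds are extended to maximal exact runs on their diagonal,
#' and runs on the same diagonal are chained when the bases between them
#' (counted as mismatches) stay within a budget of `max_mismatch_rate` x
#' chained length. Arms therefore always start and end in an exact stretch
#' of at least the seed length, which keeps a planted exact repeat from
#' bleeding into its random flanks under the mismatch budget. Overlapping
#' (hairpin-contiguous) arms are trimmed so that copy 1 always ends strictly
#' before copy 2 starts; pairs contained in a longer pair are dropped.
#'
#' @param promoter Sequence to scan (character). Coordinates in the result
#'   are `offset` + string position, so passing `offset = -promoter_len - 1`
#'   reports promoter coordinates directly (use [promoter_offset()]).
#' @param min_len Minimum arm length (nt).
#' @param max_mismatch_rate Allowed mismatches per arm length.
#' @param offset Added to every reported coordinate.
#' @param seed_k Seed k-mer size.
#' @return A tibble with one row per pair (`copy1_start`, `copy1_end`,
#'   `copy2_start`, `copy2_end`, `length`, `mismatches`, `separation`),
#'   sorted by decreasing length.
#'
#' @details `separation` is defined as `start(copy2) - end(copy1)` on the
#'   signed coordinate scale, the convention that reproduces the published
#'   3611-bp separation between copies ending at -4413 and starting at -802.
#' @export
find_inverted_repeats <- function(promoter, min_len = 100L,
                                  max_mismatch_rate = 0.02, offset = 0L,
                                  seed_k = 20L) {
  n <- nchar(promoter)
  if (n < 2L * min_len) return(new_repeat_pair_tbl())
  rc <- revcomp(promoter)
  sv <- chars(promoter)
  rv <- chars(rc)
  k <- min(seed_k, min_len)
  sk <- kmer_positions(promoter, k)
  rk <- kmer_positions(rc, k)
  # all (i, j) with S[i..i+k-1] == revcomp(S)[j..j+k-1]
  rk_index <- split(seq_along(rk), rk)
  hits_i <- integer(0); hits_j <- integer(0)
  shared <- intersect(names(rk_index), unique(sk))
  if (length(shared) == 0) return(new_repeat_pair_tbl())
  sk_index <- split(seq_along(sk), sk)
  for (key in shared) {
    is_ <- sk_index[[key]]
    js <- rk_index[[key]]
    hits_i <- c(hits_i, rep(is_, each = length(js)))
    hits_j <- c(hits_j, rep(js, times = length(is_)))
  }
  d_all <- hits_i - hits_j
  pairs <- list()
  min_run <- k
  for (d in unique(d_all)) {
    hits <- hits_i[d_all == d]
    runs <- exact_runs_from_seeds(sv, rv, hits, d)
    runs <- runs[vapply(runs, function(r) r[2] - r[1] + 1L, integer(1)) >= min_run]
    for (run in chain_runs(runs, max_mismatch_rate)) {
      ab <- trim_self_overlap(run[1], run[2], d, n)
      if (is.null(ab)) next
      # recount mismatches after trimming
      mm <- sum(sv[ab[1]:ab[2]] != rv[(ab[1]:ab[2]) - d])
      if (ab[2] - ab[1] + 1L >= min_len &&
          mm <= floor(max_mismatch_rate * (ab[2] - ab[1] + 1L))) {
        pairs[[length(pairs) + 1L]] <- run_to_pair(ab[1], ab[2], d, n, mm, offset)
      }
    }
  }
  canonicalise_pairs(dplyr::bind_rows(pairs))
}

#' Promoter-coordinate offset for a promoter ending at -1
#'
#' @param promoter_len Length of the promoter sequence.
#' @return The `offset` to pass to [find_inverted_repeats()] so positions are
#'   reported on the signed promoter scale (+1 = A of ATG, no position 0).
#' @export
promoter_offset <- function(promoter_len) -as.integer(promoter_len) - 1L

#' Exhaustive inverted-repeat enumeration (test oracle)
#'
#' Scans the full boolean match matrix of the sequence against its reverse
#' complement, diagonal by diagonal, enumerating every exact run directly
#' from the matrix, then applies the same run-chaining rule as the fast
#' finder. Deliberately brute force (O(n^2)); refuses sequences longer than
#' 2000 nt.
#'
#' @inheritParams find_inverted_repeats
#' @param min_run Minimum exact-run length for a chain endpoint; defaults
#'   to the fast finder's effective seed size.
#' @return Same shape as [find_inverted_repeats()].
#' @export
brute_force_inverted_repeats <- function(promoter, min_len = 4L,
                                         max_mismatch_rate = 0,
                                         offset = 0L,
                                         min_run = min(20L, min_len)) {
  n <- nchar(promoter)
  if (n > 2000L) abort("brute-force oracle refuses sequences > 2000 nt")
  if (n < 2L * min_len) return(new_repeat_pair_tbl())
  sv <- chars(promoter)
  rv <- chars(revcomp(promoter))
  M <- outer(sv, rv, "==")
  pairs <- list()
  for (d in (-(n - 1L)):(n - 1L)) {
    i_range <- max(1L, 1L + d):min(n, n + d)
    v <- M[cbind(i_range, i_range - d)]
    r <- rle(v)
    ends_at <- cumsum(r$lengths)
    runs <- list()
    for (q in seq_along(r$lengths)) {
      if (!r$values[q] || r$lengths[q] < min_run) next
      b <- i_range[ends_at[q]]
      runs[[length(runs) + 1L]] <- c(b - r$lengths[q] + 1L, b)
    }
    for (run in chain_runs(runs, max_mismatch_rate)) {
      ab <- trim_self_overlap(run[1], run[2], d, n)
      if (is.null(ab)) next
      mm <- sum(sv[ab[1]:ab[2]] != rv[(ab[1]:ab[2]) - d])
      if (ab[2] - ab[1] + 1L >= min_len &&
          mm <= floor(max_mismatch_rate * (ab[2] - ab[1] + 1L))) {
        pairs[[length(pairs) + 1L]] <- run_to_pair(ab[1], ab[2], d, n, mm, offset)
      }
    }
  }
  canonicalise_pairs(dplyr::bind_rows(pairs))
}

#' Stem-loop report for repeat pairs
#'
#' One row per pair: stem (arm) length, loop length (the separation between
#' the arms, i.e. the bases available to form the loop), and mismatch count.
#'
#' @param pairs Tibble from [find_inverted_repeats()].
#' @param path Optional TSV path; when given the report is also written out.
#' @return The report tibble, invisibly if `path` is given.
#' @export
loop_report <- function(pairs, path = NULL) {
  rep_tb <- pairs |>
    transmute(stem_length = length,
              loop_length = copy2_start - copy1_end,
              mismatches = mismatches,
              copy1 = sprintf("%d..%d", copy1_start, copy1_end),
              copy2 = sprintf("%d..%d", copy2_start, copy2_end))
  if (!is.null(path)) {
    readr::write_tsv(rep_tb, path)
    return(invisible(rep_tb))
  }
  rep_tb
}
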