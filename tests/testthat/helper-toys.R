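# Small in-code fixtures shared across test files.

# A toy multi-exon gene with GT-AG introns and clean flanks.
mk_toy_gene <- function(n_ex = 3, ex_len = 30, in_len = 60, flank = 50) {
  exs <- replicate(n_ex, random_dna(ex_len))
  ins <- if (n_ex > 1) {
    replicate(n_ex - 1, paste0("GT", random_dna(in_len - 4), "AG"))
  } else character(0)
  body <- exs[1]
  if (n_ex > 1) body <- paste0(exs[1], paste0(ins, exs[-1], collapse = ""))
  list(genomic = paste0(random_dna(flank), body, random_dna(flank)),
       cdna = paste(exs, collapse = ""),
       exon_sizes = rep(ex_len, n_ex))
}

# A sequence with one planted inverted-repeat pair and guard mismatches at
# the arm boundaries, so the planted pair is exactly maximal.
mk_planted_ir <- function(total_len, arm_len, gap_len, lead = 100) {
  arm <- random_dna(arm_len)
  s <- paste0(random_dna(lead), arm, random_dna(gap_len), revcomp(arm),
              random_dna(total_len - lead - 2 * arm_len - gap_len))
  c1s <- lead + 1L
  c1e <- lead + arm_len
  c2s <- c1e + gap_len + 1L
  c2e <- c2s + arm_len - 1L
  guard <- function(s, pos, partner) {
    if (pos < 1 || pos > nchar(s)) return(s)
    bad <- revcomp(substr(s, partner, partner))
    if (substr(s, pos, pos) == bad) {
      substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), bad)[1]
    }
    s
  }
  s <- guard(s, c2s - 1L, c1e + 1L)
  s <- guard(s, c1s - 1L, c2e + 1L)
  list(seq = s, copy1 = c(c1s, c1e), copy2 = c(c2s, c2e))
}

# Primer panel rows used throughout the screen tests.
screen_panel <- function() dplyr::filter(ple_primers(), id %in% c(1L, 2L))

# One positive clone (vector + full gene unit) for screening tests.
mk_positive_clone <- function(seed = 1063) {
  spec <- cluster_spec(gene_order = "PLE-1", seed = seed)
  g <- generate_gene(spec, "PLE-1")
  generate_bac_clones(g$seq,
                      data.frame(clone_id = "pos", start = 1,
                                 end = nchar(g$seq)))$clones[[1]]
}
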