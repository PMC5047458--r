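# BAC clone assembly: vector trimming, suffix-prefix overlap detection and
# linearisation of the overlap graph into ordered gene clusters.

locate_vector <- function(clone_seq, vector_seq) {
  subj <- Biostrings::DNAString(clone_seq)
  hit <- Biostrings::matchPattern(vector_seq, subj)
  if (length(hit) > 0) {
    return(list(start = Biostrings::start(hit)[1],
                end = Biostrings::end(hit)[1], identity = 100))
  }
  # tolerant search: anchor the vector ends, then align the spanned region
  vl <- nchar(vector_seq)
  alen <- min(60L, vl)
  for (mm in c(2L, 6L)) {
    h1 <- Biostrings::matchPattern(substr(vector_seq, 1, alen), subj,
                                   max.mismatch = mm)
    h2 <- Biostrings::matchPattern(substr(vector_seq, vl - alen + 1L, vl),
                                   subj, max.mismatch = mm)
    if (length(h1) == 0 || length(h2) == 0) next
    for (s in Biostrings::start(h1)) {
      for (e in Biostrings::end(h2)) {
        if (e > s && abs((e - s + 1L) - vl) < 0.1 * vl) {
          id <- pairwise_identity(substr(clone_seq, s, e), vector_seq, "nt")
          return(list(start = s, end = e, identity = id$identity))
        }
      }
    }
  }
  NULL
}

#' Trim the cloning vector from a BAC clone sequence
#'
#' Locates the single best occurrence of the vector (exact match first,
#' then an anchored tolerant search), removes it, and returns the insert
#' with its original orientation preserved; the two flanks of an internal
#' vector hit are re-joined, consistent with an arbitrarily linearised
#' circular clone. If no occurrence reaches `min_identity` the input is
#' returned unchanged with a warning flag.
#'
#' @param clone_seq Clone sequence (character).
#' @param vector_seq Vector sequence; defaults to the bundled synthetic
#'   pCC1BAC stand-in.
#' @param min_identity Minimum percent identity for a vector call.
#' @return A list: `insert` (character), `vector_interval` (c(start, end) or
#'   NULL), `vector_found` (logical).
#' @export
trim_vector <- function(clone_seq, vector_seq = ple_vector(),
                        min_identity = 95) {
  if (nchar(vector_seq) == 0) abort("vector sequence is empty")
  hit <- locate_vector(clone_seq, vector_seq)
  if (is.null(hit)) hit <- locate_vector(clone_seq, revcomp(vector_seq))
  if (is.null(hit) || hit$identity < min_identity) {
    warn("no vector occurrence found; returning input unchanged")
    return(list(insert = clone_seq, vector_interval = NULL,
                vector_found = FALSE))
  }
  left <- if (hit$start > 1) substr(clone_seq, 1, hit$start - 1L) else ""
  right <- if (hit$end < nchar(clone_seq)) {
    substr(clone_seq, hit$end + 1L, nchar(clone_seq))
  } else ""
  list(insert = paste0(left, right),
       vector_interval = c(hit$start, hit$end), vector_found = TRUE)
}

# Modal diagonal between two sequences from shared k-mers; NULL if too few.
shared_diagonal <- function(a, b, k = 31L, min_hits = 20L) {
  ka <- kmer_positions(a, k)
  kb <- kmer_positions(b, k)
  mm <- match(kb, ka)
  jb <- which(!is.na(mm))
  if (length(jb) < min_hits) return(NULL)
  d <- mm[jb] - jb  # start of B relative to A, 0-based
  tab <- sort(table(d), decreasing = TRUE)
  mode_d <- as.integer(names(tab)[1])
  if (tab[1] < min_hits) return(NULL)
  mode_d
}

# Identity of the implied overlap at diagonal d (B starts at A position
# d + 1); substitution-only comparison.
overlap_at_diagonal <- function(a, b, d) {
  la <- nchar(a); lb <- nchar(b)
  if (d >= 0) {
    len <- min(la - d, lb)
    if (len <= 0) return(NULL)
    sa <- substr(a, d + 1L, d + len)
    sb <- substr(b, 1L, len)
  } else {
    len <- min(lb + d, la)
    if (len <= 0) return(NULL)
    sa <- substr(a, 1L, len)
    sb <- substr(b, -d + 1L, -d + len)
  }
  va <- chars(sa); vb <- chars(sb)
  matches <- sum(va == vb)
  list(length = len, identity = round(100 * matches / len, 1),
       mismatches = len - matches)
}

#' Detect pairwise end-overlaps among clone inserts
#'
#' Candidate pairs are found by shared 31-mer seeds; the modal seed diagonal
#' implies the overlap layout, which is then verified base by base
#' (substitution-only model). Both orientations of each pair are tried and
#' the better one kept; each unordered pair is reported once.
#'
#' @param inserts Named character vector of vector-trimmed insert sequences.
#' @param min_overlap Minimum overlap length (nt).
#' @param min_identity Minimum percent identity over the overlap.
#' @return A tibble with one row per overlap: `cloneA`, `cloneB`, `endA`,
#'   `endB` ("5p"/"3p"; which end of each clone is shared), `orientation`
#'   ("+" if B overlaps A as given, "-" if as reverse complement),
#'   `diagonal` (start of B relative to A, 0-based, in A coordinates),
#'   `length`, `identity`, `gaps`.
#' @export
pairwise_overlaps <- function(inserts, min_overlap = 2000L,
                              min_identity = 99) {
  ids <- names(inserts)
  if (length(inserts) < 2) abort("need at least two inserts")
  rows <- list()
  for (i in seq_along(inserts)) {
    for (j in seq_along(inserts)) {
      if (j <= i) next
      best <- NULL
      for (orient in c("+", "-")) {
        b <- if (orient == "+") inserts[[j]] else revcomp(inserts[[j]])
        d <- shared_diagonal(inserts[[i]], b)
        if (is.null(d)) next
        ov <- overlap_at_diagonal(inserts[[i]], b, d)
        if (is.null(ov)) next
        if (ov$length >= min_overlap && ov$identity >= min_identity &&
            (is.null(best) || ov$length > best$length)) {
          best <- c(ov, list(orientation = orient, diagonal = d))
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- tibble(
          cloneA = ids[i], cloneB = ids[j],
          endA = if (best$diagonal >= 0) "3p" else "5p",
          endB = if (best$diagonal >= 0) "5p" else "3p",
          orientation = best$orientation, diagonal = best$diagonal,
          length = best$length, identity = best$identity, gaps = 0L)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(cloneA = character(), cloneB = character(),
                  endA = character(), endB = character(),
                  orientation = character(), diagonal = integer(),
                  length = integer(), identity = numeric(), gaps = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Order clones into gene clusters from their overlaps
#'
#' Treats clones as nodes and overlaps as edges; each connected component
#' must be a simple path (the published clone layouts are), which is then
#' linearised: every clone gets an orientation and a signed offset on the
#' cluster's common coordinate frame, and the cluster's gene order is read
#' off the clone offsets plus the per-clone gene annotations.
#'
#' @param overlaps Tibble from [pairwise_overlaps()].
#' @param clone_genes Tibble with columns `clone_id`, `gene_id`, `position`
#'   (representative position of the gene within the clone insert, e.g. the
#'   midpoint of the annotated gene span).
#' @param clone_lengths Named integer vector of insert lengths.
#' @return A list of clusters, each a list with `clones` (tibble:
#'   `clone_id`, `orientation`, `offset`) and `genes` (character vector in
#'   positional order). Branching or cyclic components raise an error
#'   naming the clones involved.
#' @export
order_clones <- function(overlaps, clone_genes, clone_lengths) {
  ids <- names(clone_lengths)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(overlaps))) {
    a <- overlaps$cloneA[r]; b <- overlaps$cloneB[r]
    adj[[a]] <- c(adj[[a]], r)
    adj[[b]] <- c(adj[[b]], r)
  }
  deg <- lengths(adj)
  if (any(deg > 2)) {
    abort(sprintf("ambiguous clone order: branching at %s",
                  paste(ids[deg > 2], collapse = ", ")))
  }
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  clusters <- list()
  for (root in ids) {
    if (seen[root]) next
    # walk the component from an endpoint (or anywhere if a single node)
    comp <- root
    repeat {
      grew <- FALSE
      for (r in seq_len(nrow(overlaps))) {
        a <- overlaps$cloneA[r]; b <- overlaps$cloneB[r]
        if (a %in% comp && !(b %in% comp)) { comp <- c(comp, b); grew <- TRUE }
        if (b %in% comp && !(a %in% comp)) { comp <- c(comp, a); grew <- TRUE }
      }
      if (!grew) break
    }
    seen[comp] <- TRUE
    edges <- which(overlaps$cloneA %in% comp | overlaps$cloneB %in% comp)
    if (length(edges) != length(comp) - 1L) {
      abort(sprintf("ambiguous clone order: cycle among %s",
                    paste(comp, collapse = ", ")))
    }
    start <- comp[which(deg[comp] <= 1L)][1]
    if (is.na(start)) start <- comp[1]
    placed <- tibble(clone_id = start, orientation = "+", offset = 0)
    frontier <- start
    used_edge <- rep(FALSE, nrow(overlaps))
    while (length(frontier) > 0) {
      cur <- frontier[1]; frontier <- frontier[-1]
      cur_row <- placed[placed$clone_id == cur, ]
      for (r in adj[[cur]]) {
        if (used_edge[r]) next
        used_edge[r] <- TRUE
        a <- overlaps$cloneA[r]; b <- overlaps$cloneB[r]
        other <- if (a == cur) b else a
        if (other %in% placed$clone_id) next
        d <- overlaps$diagonal[r]
        flip <- overlaps$orientation[r] == "-"
        # express the edge relative to `cur`: d_rel is the 0-based start of
        # `other` (flipped if orient_rel == "-") within cur's stored sequence
        if (a == cur) {
          d_rel <- d
          orient_rel <- if (flip) "-" else "+"
        } else if (!flip) {
          d_rel <- -d
          orient_rel <- "+"
        } else {
          d_rel <- d + clone_lengths[[cur]] - clone_lengths[[other]]
          orient_rel <- "-"
        }
        if (cur_row$orientation == "+") {
          off <- cur_row$offset + d_rel
          orient <- orient_rel
        } else {
          off <- cur_row$offset + clone_lengths[[cur]] - d_rel -
            clone_lengths[[other]]
          orient <- if (orient_rel == "+") "-" else "+"
        }
        placed <- dplyr::bind_rows(placed,
                                   tibble(clone_id = other,
                                          orientation = orient, offset = off))
        frontier <- c(frontier, other)
      }
    }
    placed$offset <- placed$offset - min(placed$offset)
    genes_here <- clone_genes |> filter(clone_id %in% comp) |>
      select(clone_id, gene_id, position)
    gene_pos <- purrr::pmap_dfr(genes_here, function(clone_id, gene_id, position) {
      row <- placed[placed$clone_id == clone_id, ]
      p <- if (row$orientation == "+") row$offset + position else
        row$offset + clone_lengths[[clone_id]] - position + 1L
      tibble(gene_id = gene_id, master_pos = p)
    })
    gene_order <- character(0)
    if (nrow(gene_pos) > 0) {
      gene_pos <- gene_pos |> arrange(master_pos)
      # merge repeated sightings of the same gene from overlapping clones
      keep <- rep(TRUE, nrow(gene_pos))
      for (q in seq_len(nrow(gene_pos))[-1]) {
        prev <- which(keep & gene_pos$gene_id == gene_pos$gene_id[q] &
                        abs(gene_pos$master_pos - gene_pos$master_pos[q]) < 20000)
        if (length(setdiff(prev, q)) > 0) keep[q] <- FALSE
      }
      gene_order <- gene_pos$gene_id[keep]
    }
    clusters[[length(clusters) + 1L]] <-
      list(clones = placed |> arrange(offset), genes = gene_order)
  }
  clusters
}
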