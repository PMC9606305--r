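# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by enumeration / exhaustive dynamic
# programming, not by calling the code paths they check.

# --- oriented-edge expansion + brute-force simple-bubble enumeration ------

expand_oriented <- function(graph) {
  l <- graph$links
  if (!nrow(l)) return(data.frame(from = character(), to = character()))
  flip <- function(o) ifelse(o == "+", "-", "+")
  unique(rbind(
    data.frame(from = paste0(l$from, l$from_orient),
               to = paste0(l$to, l$to_orient)),
    data.frame(from = paste0(l$to, flip(l$to_orient)),
               to = paste0(l$from, flip(l$from_orient)))
  ))
}

# enumerate every pair of vertex-disjoint clean-interior directed paths
# between every (source with out-degree 2, sink with in-degree 2) pair
brute_bubbles <- function(graph) {
  ed <- expand_oriented(graph)
  if (!nrow(ed)) return(character(0))
  nodes <- unique(c(ed$from, ed$to))
  adj <- split(ed$to, factor(ed$from, levels = nodes))
  indeg <- table(factor(ed$to, levels = nodes))
  outdeg <- table(factor(ed$from, levels = nodes))
  unary <- function(v) indeg[[v]] == 1 && outdeg[[v]] == 1
  seg <- function(v) substr(v, 1, nchar(v) - 1)

  all_paths <- function(s, t) {
    res <- list()
    rec <- function(cur, visited, interior) {
      for (nx in adj[[cur]]) {
        if (nx == t) {
          res[[length(res) + 1]] <<- interior
        } else if (!(nx %in% visited) && nx != s && nx != t) {
          rec(nx, c(visited, nx), c(interior, nx))
        }
      }
    }
    rec(s, character(0), character(0))
    res
  }

  segs <- character(0)
  for (s in nodes) {
    if (outdeg[[s]] != 2) next
    for (t in nodes) {
      if (s == t || indeg[[t]] != 2) next
      ps <- all_paths(s, t)
      if (length(ps) < 2) next
      for (i in seq_along(ps)) {
        for (j in seq_along(ps)) {
          if (i >= j) next
          p1 <- ps[[i]]; p2 <- ps[[j]]
          if (length(intersect(p1, p2))) next
          if (length(p1) && !all(vapply(p1, unary, TRUE))) next
          if (length(p2) && !all(vapply(p2, unary, TRUE))) next
          f1 <- if (length(p1)) p1[1] else t
          f2 <- if (length(p2)) p2[1] else t
          if (identical(f1, f2)) next
          segs <- c(segs, seg(c(s, t, p1, p2)))
        }
      }
    }
  }
  sort(unique(segs))
}

random_test_graph <- function(n_seg, n_link) {
  ids <- letters[seq_len(n_seg)]
  segments <- data.frame(id = ids, length = 1000L)
  links <- data.frame(
    from = sample(ids, n_link, replace = TRUE),
    from_orient = sample(c("+", "-"), n_link, replace = TRUE),
    to = sample(ids, n_link, replace = TRUE),
    to_orient = sample(c("+", "-"), n_link, replace = TRUE)
  )
  links <- links[links$from != links$to, , drop = FALSE]
  assembly_graph(segments, links)
}

# --- optimal global alignment oracle (match count) ------------------------

oracle_global_matches <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(al)
}

# --- controlled mutation planting (independent of the simulator) ----------

# substitutions at given 0-based positions; returns mutated string
plant_substitutions <- function(sequence, pos0) {
  r <- charToRaw(sequence)
  alphabet <- as.raw(c(65L, 67L, 71L, 84L))
  idx <- pos0 + 1L
  code <- match(r[idx], alphabet)
  r[idx] <- alphabet[(code %% 4L) + 1L]
  rawToChar(r)
}

# insert random bases after given 0-based positions (descending order)
plant_insertions <- function(sequence, pos0, len) {
  r <- charToRaw(sequence)
  for (p in sort(pos0, decreasing = TRUE)) {
    r <- append(r, charToRaw(random_dna(len)), after = p + 1L)
  }
  rawToChar(r)
}

# positions spaced at least `gap` apart within [lo, hi]
spaced_positions <- function(n, lo, hi, gap) {
  stopifnot(lo + (n - 1) * gap <= hi)
  base <- seq(lo, by = gap, length.out = n)
  base + sample.int(gap %/% 2, n, replace = TRUE)
}

# --- small shared-contig pangenome builder ---------------------------------

# genomes as named lists of contig vectors built from shared random blocks
build_shared_genomes <- function(blocks, layout) {
  lapply(layout, function(contig_names) {
    out <- blocks[contig_names]
    names(out) <- contig_names
    out
  })
}
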