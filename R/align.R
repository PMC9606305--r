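#' Pairwise whole-genome alignment by seed-chain-extend
#'
#' Finds exact seed matches of length >= `min_seed` (unique in both sequences
#' in `unique_anchor` mode, all occurrences in `maxmatch` mode), chains them
#' per contig pair and strand, closes inter-anchor gaps by small global
#' alignments (match +1, mismatch -1, gap -2) and extends chain ends
#' gaplessly. Both strands are searched via reverse complement of the query.
#' N bases never count as matches or substitutions.
#'
#' @param ref,qry Reference/query sequence sets: DNAStringSet or named
#'   character vector (a single unnamed sequence is also accepted).
#' @param mode `"unique_anchor"` (nucmer --mum analogue, the default) or
#'   `"maxmatch"` (all seed occurrences; use when the query set may be
#'   internally redundant).
#' @param min_seed Seed length, >= 11 (default 19).
#' @param max_gap Largest inter-anchor gap bridged within one chain (bp).
#' @param min_chain_score Minimum chain score for a block to be emitted.
#' @param keep_match_pos If TRUE, each block carries the reference positions
#'   of its match columns (list column `match_pos`); needed by
#'   [bin_retrieval()].
#' @return Data frame of alignment blocks: `ref_contig`, `qry_contig`,
#'   0-based half-open `ref_start`/`ref_end`/`qry_start`/`qry_end`, `strand`,
#'   `matches`, `mismatches` (substitution columns), `aligned_length`
#'   (all columns incl. gaps) and `identity` = matches / aligned_length.
#' @export
align <- function(ref, qry, mode = c("unique_anchor", "maxmatch"),
                  min_seed = 19, max_gap = 1000, min_chain_score = 60,
                  keep_match_pos = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_seed >= 11, min_seed <= 31)
  ref <- as_seq_chr(ref, "ref")
  qry <- as_seq_chr(qry, "qry")
  res <- align_sets_cpp(names(ref), unname(ref), names(qry), unname(qry),
                        as.integer(min_seed), mode == "unique_anchor",
                        64L, as.integer(max_gap),
                        as.integer(min_chain_score), keep_match_pos)
  blocks <- data.frame(
    ref_contig = res$ref_contig, qry_contig = res$qry_contig,
    ref_start = res$ref_start, ref_end = res$ref_end,
    qry_start = res$qry_start, qry_end = res$qry_end,
    strand = res$strand, matches = res$matches,
    mismatches = res$mismatches, aligned_length = res$aligned_length,
    stringsAsFactors = FALSE
  )
  blocks$identity <- ifelse(blocks$aligned_length > 0,
                            blocks$matches / blocks$aligned_length, 0)
  if (keep_match_pos) blocks$match_pos <- res$match_pos
  blocks
}

as_seq_chr <- function(x, what) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  ids <- names(x)
  x <- toupper(as.character(x))
  names(x) <- ids
  if (is.null(names(x))) {
    if (length(x) != 1L) stop(what, " sequences must be named")
    names(x) <- what
  }
  if (any(nchar(x) < 1L)) stop(what, " contains an empty sequence")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " sequence(s) contain symbols outside {A,C,G,T,N}: ",
         paste(names(x)[bad], collapse = ", "))
  }
  x
}

#' Best-bidirectional filtering of alignment blocks
#'
#' Greedy retention by descending match count; a block is kept only if its
#' overlap with every already-retained block is at most `tolerance_bp` on
#' each filtered axis (reference and/or query). With `axes = "both"` this is
#' the analogue of delta-filter -r -q; `"ref"` alone corresponds to -r.
#'
#' @param blocks Block data frame from [align()].
#' @param axes Which axes must be near-disjoint: `"both"`, `"ref"` or
#'   `"qry"`.
#' @param tolerance_bp Permitted residual overlap per axis (default 50).
#' @return The retained subset of `blocks`.
#' @export
best_bidirectional <- function(blocks, axes = c("both", "ref", "qry"),
                               tolerance_bp = 50) {
  axes <- match.arg(axes)
  if (nrow(blocks) <= 1) return(blocks)
  ord <- order(-blocks$matches, blocks$ref_start, blocks$qry_start)
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (axes %in% c("both", "ref") &&
          blocks$ref_contig[i] == blocks$ref_contig[j]) {
        ov <- min(blocks$ref_end[i], blocks$ref_end[j]) -
          max(blocks$ref_start[i], blocks$ref_start[j])
        if (ov > tolerance_bp) { ok <- FALSE; break }
      }
      if (axes %in% c("both", "qry") &&
          blocks$qry_contig[i] == blocks$qry_contig[j]) {
        ov <- min(blocks$qry_end[i], blocks$qry_end[j]) -
          max(blocks$qry_start[i], blocks$qry_start[j])
        if (ov > tolerance_bp) { ok <- FALSE; break }
      }
    }
    if (ok) keep <- c(keep, i)
  }
  blocks[sort(keep), , drop = FALSE]
}

#' Summarize filtered blocks into ANI, coverage and similarity index
#'
#' ANI is the matched fraction of aligned columns
#' (sum(matches) / sum(aligned_length)); aligned bases per side come from
#' merged interval coverage; maximum alignment coverage is the larger of the
#' two divided by the shorter total sequence length; the similarity index is
#' their product.
#'
#' @param blocks Best-bidirectional-filtered block data frame.
#' @param ref_len,qry_len Total sequence length of each side (bp).
#' @return A [pairwise_summary()].
#' @export
summarize_alignment <- function(blocks, ref_len, qry_len) {
  if (nrow(blocks) == 0) {
    return(pairwise_summary(0, 0, aligned_bases_ref = 0L,
                            aligned_bases_qry = 0L))
  }
  ani <- sum(blocks$matches) / sum(blocks$aligned_length)
  abr <- merged_span(blocks$ref_contig, blocks$ref_start, blocks$ref_end)
  abq <- merged_span(blocks$qry_contig, blocks$qry_start, blocks$qry_end)
  cov <- min(1, max(abr, abq) / min(ref_len, qry_len))
  pairwise_summary(ani, cov, aligned_bases_ref = abr, aligned_bases_qry = abq)
}

merged_span <- function(contig, start, end) {
  sum(vapply(unique(contig), function(cid) {
    sel <- contig == cid
    ir <- IRanges::reduce(IRanges::IRanges(start = start[sel] + 1L,
                                           end = end[sel]))
    sum(IRanges::width(ir))
  }, numeric(1)))
}

#' Pairwise alignment summary
#'
#' @param ani Average nucleotide identity (matched / aligned columns).
#' @param max_alignment_coverage Merged aligned span of the better-covered
#'   side over the shorter sequence length.
#' @param aligned_bases_ref,aligned_bases_qry Merged aligned bases per side.
#' @return List of class `pairwise_summary` whose `similarity_index` is
#'   `ani * max_alignment_coverage`.
#' @export
pairwise_summary <- function(ani, max_alignment_coverage,
                             aligned_bases_ref = NA_integer_,
                             aligned_bases_qry = NA_integer_) {
  stopifnot(ani >= 0, ani <= 1,
            max_alignment_coverage >= 0, max_alignment_coverage <= 1)
  structure(list(ani = ani,
                 max_alignment_coverage = max_alignment_coverage,
                 similarity_index = ani * max_alignment_coverage,
                 aligned_bases_ref = aligned_bases_ref,
                 aligned_bases_qry = aligned_bases_qry),
            class = "pairwise_summary")
}

#' @export
print.pairwise_summary <- function(x, ...) {
  cat(sprintf("ANI %.4f | max coverage %.4f | similarity index %.4f\n",
              x$ani, x$max_alignment_coverage, x$similarity_index))
  invisible(x)
}

#' Align, filter and summarize one genome pair in a single call
#'
#' @inheritParams align
#' @param axes Filtering axes passed to [best_bidirectional()].
#' @export
pairwise_compare <- function(ref, qry, mode = "unique_anchor",
                             axes = "both", min_seed = 19) {
  ref <- as_seq_chr(ref, "ref")
  qry <- as_seq_chr(qry, "qry")
  blocks <- best_bidirectional(align(ref, qry, mode = mode,
                                     min_seed = min_seed), axes = axes)
  summarize_alignment(blocks, sum(nchar(ref)), sum(nchar(qry)))
}

# One alignment call against many genomes: `ref` is indexed once and every
# contig of every genome is scanned against it; per-genome block tables are
# returned with query contig names restored. Query-side seed uniqueness is
# evaluated per contig, so batching does not change unique-anchor semantics.
align_per_genome <- function(ref, genomes, mode = "unique_anchor",
                             keep_match_pos = FALSE) {
  sep <- "\x01"
  qseqs <- character(0)
  for (g in names(genomes)) {
    s <- as_seq_chr(genomes[[g]], "genome")
    names(s) <- paste0(g, sep, names(s))
    qseqs <- c(qseqs, s)
  }
  blocks <- align(ref, qseqs, mode = mode, keep_match_pos = keep_match_pos)
  parts <- strsplit(blocks$qry_contig, sep, fixed = TRUE)
  gid <- vapply(parts, `[`, "", 1)
  blocks$qry_contig <- vapply(parts, `[`, "", 2)
  out <- lapply(names(genomes), function(g) blocks[gid == g, , drop = FALSE])
  names(out) <- names(genomes)
  out
}

total_length <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(sum(Biostrings::width(x)))
  sum(nchar(as.character(x)))
}
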