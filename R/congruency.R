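#' Conspecificity rule
#'
#' A catalog genome is conspecific with the query when ANI and maximum
#' alignment coverage strictly exceed the thresholds (defaults 0.95 and
#' 0.8).
#'
#' @param ani,cov Numeric vectors.
#' @param ani_threshold,cov_threshold Strict lower bounds.
#' @export
is_conspecific <- function(ani, cov, ani_threshold = 0.95,
                           cov_threshold = 0.8) {
  ani > ani_threshold & cov > cov_threshold
}

#' Find conspecific catalog genomes for a query contig
#'
#' Reduced search: (1) align the query against each species representative
#' of the query's genus; (2) pick the species with the highest similarity
#' index (ties: larger species cluster, then id); (3) align the query
#' against every genome of that cluster; (4) keep genomes with ANI and
#' coverage strictly above the thresholds; (5) stop after `cap` members in
#' catalog order.
#'
#' @param query Single query sequence (named character or DNAStringSet of
#'   one contig).
#' @param catalog A [genome_catalog()].
#' @param query_genus Genus label of the query (an input from upstream
#'   taxonomy).
#' @param conspecific_ani ANI threshold (default 0.95).
#' @param cov_threshold Coverage threshold (default 0.8).
#' @param genus_ani_overrides Named numeric vector of per-genus ANI
#'   thresholds; the default relaxes Collinsella to 0.94, a genus with an
#'   exceptionally high variant rate.
#' @param cap Maximum number of members retained (default 100).
#' @return List of class `conspecific_set`: `query_id`,
#'   `species_cluster_id`, `members` (data frame with `genome_id`, `ani`,
#'   `max_alignment_coverage`, `similarity_index`), `capped`.
#' @export
find_conspecific <- function(query, catalog, query_genus,
                             conspecific_ani = 0.95, cov_threshold = 0.8,
                             genus_ani_overrides = c(Collinsella = 0.94),
                             cap = 100) {
  query <- as_seq_chr(query, "query")
  stopifnot(length(query) == 1L)
  if (query_genus %in% names(genus_ani_overrides)) {
    conspecific_ani <- unname(genus_ani_overrides[query_genus])
  }
  meta <- catalog$metadata
  empty <- structure(list(query_id = names(query),
                          species_cluster_id = NA_character_,
                          members = data.frame(
                            genome_id = character(), ani = numeric(),
                            max_alignment_coverage = numeric(),
                            similarity_index = numeric()),
                          capped = FALSE, ani_threshold = conspecific_ani),
                     class = "conspecific_set")
  reps <- meta[meta$is_representative & meta$genus == query_genus, ,
               drop = FALSE]
  if (!nrow(reps)) return(empty)

  rep_blocks <- align_per_genome(query, catalog$genomes[reps$genome_id])
  rep_sum <- lapply(reps$genome_id, function(g) {
    summarize_alignment(best_bidirectional(rep_blocks[[g]], axes = "both"),
                        nchar(query), total_length(catalog$genomes[[g]]))
  })
  si <- vapply(rep_sum, `[[`, numeric(1), "similarity_index")
  cluster_size <- vapply(reps$species_cluster_id, function(cl) {
    sum(meta$species_cluster_id == cl)
  }, numeric(1))
  ord <- order(-si, -cluster_size, reps$species_cluster_id)
  best_cluster <- reps$species_cluster_id[ord[1]]

  members <- meta$genome_id[meta$species_cluster_id == best_cluster]
  mem_blocks <- align_per_genome(query, catalog$genomes[members])
  rows <- list()
  capped <- FALSE
  for (g in members) {
    s <- summarize_alignment(best_bidirectional(mem_blocks[[g]],
                                                axes = "both"),
                             nchar(query),
                             total_length(catalog$genomes[[g]]))
    if (is_conspecific(s$ani, s$max_alignment_coverage,
                       conspecific_ani, cov_threshold)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, ani = s$ani,
        max_alignment_coverage = s$max_alignment_coverage,
        similarity_index = s$similarity_index)
      if (length(rows) >= cap) { capped <- TRUE; break }
    }
  }
  out <- empty
  out$species_cluster_id <- best_cluster
  if (length(rows)) out$members <- do.call(rbind, rows)
  out$capped <- capped
  out
}

#' Presence of a contig in another genome
#'
#' A contig is present in a genome when the merged aligned span of blocks
#' with identity strictly above `min_identity` exceeds half of the contig
#' length.
#'
#' @param contig Single named sequence.
#' @param genome Sequence set of the target genome.
#' @param mode Alignment mode; member-vs-member comparisons use
#'   `"unique_anchor"` with best-bidirectional filtering, core-vs-query uses
#'   `"maxmatch"` without it (the core set may be internally redundant).
#' @param min_identity Per-block identity bound (strict; default 0.95).
#' @export
contig_present <- function(contig, genome, mode = "unique_anchor",
                           min_identity = 0.95) {
  contig <- as_seq_chr(contig, "contig")
  stopifnot(length(contig) == 1L)
  blocks <- align(genome, contig, mode = mode)
  if (mode == "unique_anchor") {
    blocks <- best_bidirectional(blocks, axes = "both")
  }
  blocks <- blocks[blocks$identity > min_identity, , drop = FALSE]
  if (!nrow(blocks)) return(FALSE)
  span <- merged_span(blocks$qry_contig, blocks$qry_start, blocks$qry_end)
  span > 0.5 * nchar(contig)
}

#' Core-contig rule
#'
#' @param length_bp Contig length.
#' @param presence_fraction Fraction of the *other* conspecific genomes the
#'   contig is present in.
#' @param min_len,presence_threshold Strict lower bounds (5000 bp, 0.8).
#' @export
is_core <- function(length_bp, presence_fraction, min_len = 5000,
                    presence_threshold = 0.8) {
  length_bp > min_len & presence_fraction > presence_threshold
}

#' Identify core contigs shared by conspecific genomes
#'
#' All-pairs alignment among member genomes; a contig's presence fraction is
#' computed over the other members (self excluded, since a contig is
#' trivially present in its own genome). Core contigs are longer than
#' `min_len` and present in more than `presence_threshold` of the other
#' members.
#'
#' @param members Named list of genome sequence sets (DNAStringSet or named
#'   character), at least 2 (>= 5 for a meaningful congruency decision).
#' @param min_len,presence_threshold Core rule parameters (5000 bp, 0.8).
#' @param min_identity,mode Presence rule parameters
#'   (see [contig_present()]).
#' @return List of class `core_contig_set`: `table` (data frame
#'   `genome_id`, `contig_id`, `length`, `presence_fraction`, `core`),
#'   `sequences` (named character vector of the core contigs, names
#'   `genome_id::contig_id`) and the parameters used.
#' @export
identify_core_contigs <- function(members, min_len = 5000,
                                  presence_threshold = 0.8,
                                  min_identity = 0.95,
                                  mode = "unique_anchor") {
  stopifnot(length(members) >= 2)
  members <- lapply(members, as_seq_chr, what = "member")
  if (any(vapply(members, length, 0L) == 0L)) {
    stop("member genome with empty sequence set")
  }
  ids <- names(members)
  n_other <- length(ids) - 1L

  # presence[[g]][contig, h]: is contig of g present in h?  One alignment
  # per unordered genome pair serves both directions (query-axis spans give
  # presence of g's contigs in h, reference-axis spans the converse), as a
  # single nucmer/delta-filter run per pair would.
  presence <- lapply(ids, function(g) {
    matrix(FALSE, nrow = length(members[[g]]), ncol = n_other,
           dimnames = list(names(members[[g]]), setdiff(ids, g)))
  })
  names(presence) <- ids
  for (hi in seq_len(length(ids) - 1L)) {
    h <- ids[hi]
    per_g <- align_per_genome(members[[h]], members[ids[-seq_len(hi)]],
                              mode = mode)
    for (g in names(per_g)) {
      blocks <- best_bidirectional(per_g[[g]], axes = "both")
      blocks <- blocks[blocks$identity > min_identity, , drop = FALSE]
      for (cid in unique(blocks$qry_contig)) {
        cb <- blocks[blocks$qry_contig == cid, , drop = FALSE]
        span <- merged_span(cb$qry_contig, cb$qry_start, cb$qry_end)
        presence[[g]][cid, h] <- span > 0.5 * nchar(members[[g]][[cid]])
      }
      for (cid in unique(blocks$ref_contig)) {
        cb <- blocks[blocks$ref_contig == cid, , drop = FALSE]
        span <- merged_span(cb$ref_contig, cb$ref_start, cb$ref_end)
        presence[[h]][cid, g] <- span > 0.5 * nchar(members[[h]][[cid]])
      }
    }
  }
  rows <- list()
  core_seqs <- character(0)
  for (g in ids) {
    contigs <- members[[g]]
    pf <- rowMeans(presence[[g]])
    core <- is_core(nchar(contigs), pf, min_len, presence_threshold)
    rows[[g]] <- data.frame(genome_id = g, contig_id = names(contigs),
                            length = unname(nchar(contigs)),
                            presence_fraction = unname(pf),
                            core = unname(core))
    sel <- names(contigs)[core]
    if (length(sel)) {
      add <- contigs[sel]
      names(add) <- paste0(g, "::", sel)
      core_seqs <- c(core_seqs, add)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, sequences = core_seqs,
                 min_len = min_len, presence_threshold = presence_threshold,
                 n_members = length(ids)),
            class = "core_contig_set")
}

#' Congruency verdict rule
#'
#' @param retrieval_rate Fraction of core contigs retrieved by the query.
#' @param n_conspecific Number of conspecific genomes found.
#' @param min_rate Inclusive acceptance bound on the retrieval rate
#'   (default 0.95; rates below it reject).
#' @param min_conspecific Inclusive minimum conspecific count (default 5;
#'   fewer reject).
#' @return `"accept"`, `"reject_low_retrieval"` or
#'   `"reject_few_conspecific"`.
#' @export
congruency_verdict <- function(retrieval_rate, n_conspecific,
                               min_rate = 0.95, min_conspecific = 5) {
  if (n_conspecific < min_conspecific) return("reject_few_conspecific")
  if (is.na(retrieval_rate) || retrieval_rate < min_rate) {
    return("reject_low_retrieval")
  }
  "accept"
}

#' Core-contig retrieval rate and congruency decision
#'
#' Aligns every core contig against the query in maxmatch mode (the core
#' set can contain redundant sequences) and counts a core contig as
#' retrieved when it is present in the query under the same presence rule
#' used to define cores (> half of its length aligned at > 95% identity).
#'
#' @param query Single named query sequence.
#' @param core A [identify_core_contigs()] result.
#' @param n_conspecific Number of conspecific genomes backing the core set.
#' @param min_rate,min_conspecific Verdict bounds (0.95, 5).
#' @param min_identity Presence identity bound (0.95).
#' @return List of class `congruency_decision`: `query_id`,
#'   `retrieval_rate`, `n_core`, `n_retrieved`, `n_conspecific`, `verdict`,
#'   `per_contig` (logical vector).
#' @export
core_retrieval_rate <- function(query, core, n_conspecific,
                                min_rate = 0.95, min_conspecific = 5,
                                min_identity = 0.95) {
  query <- as_seq_chr(query, "query")
  stopifnot(length(query) == 1L)
  seqs <- core$sequences
  if (!length(seqs)) {
    return(structure(list(query_id = names(query), retrieval_rate = NA_real_,
                          n_core = 0L, n_retrieved = 0L,
                          n_conspecific = n_conspecific,
                          verdict = congruency_verdict(NA_real_,
                                                       n_conspecific,
                                                       min_rate,
                                                       min_conspecific),
                          per_contig = logical(0)),
                     class = "congruency_decision"))
  }
  blocks <- align(query, seqs, mode = "maxmatch")
  blocks <- blocks[blocks$identity > min_identity, , drop = FALSE]
  retrieved <- vapply(names(seqs), function(cid) {
    cb <- blocks[blocks$qry_contig == cid, , drop = FALSE]
    if (!nrow(cb)) return(FALSE)
    span <- merged_span(cb$qry_contig, cb$qry_start, cb$qry_end)
    span > 0.5 * nchar(seqs[[cid]])
  }, logical(1))
  rate <- mean(retrieved)
  structure(list(query_id = names(query), retrieval_rate = rate,
                 n_core = length(retrieved),
                 n_retrieved = sum(retrieved),
                 n_conspecific = n_conspecific,
                 verdict = congruency_verdict(rate, n_conspecific,
                                              min_rate, min_conspecific),
                 per_contig = retrieved),
            class = "congruency_decision")
}

#' @export
print.congruency_decision <- function(x, ...) {
  cat(sprintf("%s: %d/%d core contigs retrieved (%.3f), %d conspecific -> %s\n",
              x$query_id, x$n_retrieved, x$n_core,
              if (is.na(x$retrieval_rate)) 0 else x$retrieval_rate,
              x$n_conspecific, x$verdict))
  invisible(x)
}

#' Culturability flags from conspecific isolate genomes
#'
#' A query has an isolate-derived conspecific when at least one catalog
#' genome flagged as isolate aligns with ANI strictly above `ani_threshold`
#' and maximum alignment coverage strictly above `cov_threshold` (note the
#' relaxed 0.6 coverage, not the 0.8 conspecificity bound).
#'
#' @param query Single named query sequence.
#' @param catalog A [genome_catalog()].
#' @param ani_threshold,cov_threshold Strict bounds (0.95, 0.6).
#' @return List with `has_isolate_conspecific` and `has_complete_isolate`.
#' @export
culturability <- function(query, catalog, ani_threshold = 0.95,
                          cov_threshold = 0.6) {
  query <- as_seq_chr(query, "query")
  meta <- catalog$metadata
  iso <- meta[meta$is_isolate, , drop = FALSE]
  has_iso <- FALSE
  has_complete <- FALSE
  if (nrow(iso)) {
    iso_blocks <- align_per_genome(query, catalog$genomes[iso$genome_id])
    for (i in seq_len(nrow(iso))) {
      s <- summarize_alignment(
        best_bidirectional(iso_blocks[[iso$genome_id[i]]], axes = "both"),
        nchar(query), total_length(catalog$genomes[[iso$genome_id[i]]]))
      if (is_conspecific(s$ani, s$max_alignment_coverage,
                         ani_threshold, cov_threshold)) {
        has_iso <- TRUE
        if (iso$is_complete[i]) has_complete <- TRUE
        if (has_complete) break
      }
    }
  }
  list(has_isolate_conspecific = has_iso,
       has_complete_isolate = has_complete)
}
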