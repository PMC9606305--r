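#' Redundancy edges from precomputed pairwise summaries
#'
#' Both thresholds are strict (>), as calibrated for redundant contigs
#' assembled from the same or pooled samples.
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `ani`,
#'   `max_alignment_coverage`.
#' @param ani_threshold,cov_threshold Strict lower bounds (defaults 0.99 and
#'   0.95).
#' @return The subset of `pairs` forming redundancy edges.
#' @export
redundancy_edges <- function(pairs, ani_threshold = 0.99,
                             cov_threshold = 0.95) {
  pairs[pairs$ani > ani_threshold &
          pairs$max_alignment_coverage > cov_threshold, , drop = FALSE]
}

#' Compute all pairwise summaries among contigs
#'
#' @param contigs DNAStringSet or named character vector of contigs.
#' @return Data frame with one row per unordered pair: `id_a`, `id_b`,
#'   `ani`, `max_alignment_coverage`, `similarity_index`.
#' @export
pairwise_summaries <- function(contigs) {
  contigs <- as_seq_chr(contigs, "contigs")
  ids <- names(contigs)
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        s <- pairwise_compare(contigs[i], contigs[j])
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], ani = s$ani,
          max_alignment_coverage = s$max_alignment_coverage,
          similarity_index = s$similarity_index)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(), id_b = character(),
                      ani = numeric(), max_alignment_coverage = numeric(),
                      similarity_index = numeric()))
  }
  do.call(rbind, rows)
}

#' Build the redundancy graph over a contig collection
#'
#' Aligns every unordered contig pair, filters best-bidirectionally and adds
#' an edge whenever ANI and maximum alignment coverage strictly exceed the
#' thresholds.
#'
#' @inheritParams pairwise_summaries
#' @inheritParams redundancy_edges
#' @return An [igraph::graph] whose vertices are all contig ids and whose
#'   edges carry `ani` attributes; the pair table is attached as the
#'   `pairs` graph attribute.
#' @export
build_redundancy_graph <- function(contigs, ani_threshold = 0.99,
                                   cov_threshold = 0.95) {
  contigs <- as_seq_chr(contigs, "contigs")
  pairs <- pairwise_summaries(contigs)
  edges <- redundancy_edges(pairs, ani_threshold, cov_threshold)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(names(contigs))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$id_a, edges$id_b),
                           ani = edges$ani)
  }
  igraph::V(g)$length <- nchar(contigs)[igraph::V(g)$name]
  g <- igraph::set_graph_attr(g, "pairs", pairs)
  g
}

#' Select representatives for each redundancy cluster
#'
#' Clusters are connected components of the redundancy graph. The
#' representative is the member with the largest sum of ANI over its
#' within-cluster edges; ties go to the longer contig, then to the
#' lexicographically smallest id.
#'
#' @param graph Graph from [build_redundancy_graph()].
#' @return Data frame with `cluster_id`, `member`, `is_representative`,
#'   `ani_sum`, `length`.
#' @export
select_representatives <- function(graph) {
  comp <- igraph::components(graph)
  ani_sum <- igraph::strength(graph, weights = igraph::E(graph)$ani)
  df <- data.frame(member = igraph::V(graph)$name,
                   cluster_id = comp$membership,
                   ani_sum = as.numeric(ani_sum),
                   length = igraph::V(graph)$length)
  df <- df[order(df$cluster_id, -df$ani_sum, -df$length, df$member), ]
  df$is_representative <- !duplicated(df$cluster_id)
  rownames(df) <- NULL
  df[, c("cluster_id", "member", "is_representative", "ani_sum", "length")]
}

#' Dereplicate a contig collection
#'
#' @inheritParams build_redundancy_graph
#' @return List with `clusters` (the [select_representatives()] table) and
#'   `representatives` (character vector of retained contig ids).
#' @export
dereplicate <- function(contigs, ani_threshold = 0.99,
                        cov_threshold = 0.95) {
  g <- build_redundancy_graph(contigs, ani_threshold, cov_threshold)
  cl <- select_representatives(g)
  list(clusters = cl,
       representatives = cl$member[cl$is_representative],
       graph = g)
}
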