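#' Thresholds for the biological-prior filter
#'
#' Defaults are the published first-stage criteria: length >= 100 kbp,
#' >= 100 universal single-copy marker proteins (bac120 or arc122, whichever
#' namespace dominates the contig's hits), presence of all of 5S/16S/23S
#' rRNA, and >= 20 distinct non-pseudo tRNA isotypes. All length/count
#' thresholds are inclusive (>=).
#'
#' @param min_length_bp Minimum contig length (default 100000).
#' @param min_marker_count Minimum marker count in the dominant namespace
#'   (default 100).
#' @param required_rrna_types rRNA types that must each have at least one
#'   interval (default all of 5S, 16S, 23S).
#' @param min_trna_types Minimum number of distinct non-pseudo tRNA isotypes
#'   (default 20).
#' @param rrna_mode `"all"` (every listed type required, default) or
#'   `"any"` (at least one).
#' @export
prior_thresholds <- function(min_length_bp = 100000,
                             min_marker_count = 100,
                             required_rrna_types = c("5S", "16S", "23S"),
                             min_trna_types = 20,
                             rrna_mode = c("all", "any")) {
  rrna_mode <- match.arg(rrna_mode)
  stopifnot(min_length_bp > 0, min_marker_count > 0, min_trna_types > 0,
            length(required_rrna_types) >= 1)
  structure(list(min_length_bp = min_length_bp,
                 min_marker_count = min_marker_count,
                 required_rrna_types = required_rrna_types,
                 min_trna_types = min_trna_types,
                 rrna_mode = rrna_mode),
            class = "prior_thresholds")
}

#' Count distinct non-pseudo tRNA isotypes
#'
#' Pseudo-flagged records are excluded before counting distinct isotypes.
#'
#' @param annotation An [annotation_set()].
#' @return Integer count of distinct isotypes among non-pseudo tRNAs.
#' @export
count_trna_types <- function(annotation) {
  t <- annotation$trna
  if (is.null(t) || !nrow(t)) return(0L)
  length(unique(t$isotype[!t$pseudo]))
}

# marker count within the dominant namespace (bac120 vs arc122), so the
# threshold applies to one domain's marker set
dominant_marker_count <- function(marker_ids) {
  ns <- ifelse(grepl("^arc122", marker_ids), "arc122", "bac120")
  if (!length(marker_ids)) return(0L)
  max(table(ns))
}

#' Apply the biological-prior filter to one circular contig
#'
#' Every criterion is evaluated (no short-circuiting) so the report lists
#' all failures: circularity, length, marker count, rRNA presence, tRNA
#' isotype count, assembly bubble and repeat status.
#'
#' @param contig_id Contig id.
#' @param length_bp Contig length in bp.
#' @param circular Is the contig circular?
#' @param annotation [annotation_set()] for the contig (NULL treated as
#'   empty).
#' @param in_bubble,is_repeat Assembly-graph screening flags.
#' @param thresholds A [prior_thresholds()].
#' @return A [filter_report()] for stage `"prior_filter"`.
#' @export
apply_prior_filter <- function(contig_id, length_bp, circular = TRUE,
                               annotation = NULL, in_bubble = FALSE,
                               is_repeat = FALSE,
                               thresholds = prior_thresholds()) {
  if (is.null(annotation)) {
    annotation <- annotation_set(contig_id)
  }
  n_markers <- dominant_marker_count(annotation$marker_ids)
  n_trna <- count_trna_types(annotation)
  rrna_present <- thresholds$required_rrna_types %in% annotation$rrna$type
  rrna_ok <- if (thresholds$rrna_mode == "all") {
    all(rrna_present)
  } else {
    any(rrna_present)
  }
  missing_rrna <- thresholds$required_rrna_types[!rrna_present]

  reasons <- rbind(
    data.frame(criterion = "circular",
               observed = as.character(circular), threshold = "TRUE",
               passed = isTRUE(circular)),
    data.frame(criterion = "length_bp",
               observed = as.character(length_bp),
               threshold = paste0(">=", thresholds$min_length_bp),
               passed = length_bp >= thresholds$min_length_bp),
    data.frame(criterion = "marker_count",
               observed = as.character(n_markers),
               threshold = paste0(">=", thresholds$min_marker_count),
               passed = n_markers >= thresholds$min_marker_count),
    data.frame(criterion = "rRNA",
               observed = if (length(missing_rrna)) {
                 paste("missing", paste(missing_rrna, collapse = ","))
               } else "all present",
               threshold = paste(thresholds$rrna_mode, "of",
                                 paste(thresholds$required_rrna_types,
                                       collapse = ",")),
               passed = rrna_ok),
    data.frame(criterion = "trna_types",
               observed = as.character(n_trna),
               threshold = paste0(">=", thresholds$min_trna_types),
               passed = n_trna >= thresholds$min_trna_types),
    data.frame(criterion = "assembly_bubble",
               observed = as.character(in_bubble), threshold = "FALSE",
               passed = !isTRUE(in_bubble)),
    data.frame(criterion = "assembly_repeat",
               observed = as.character(is_repeat), threshold = "FALSE",
               passed = !isTRUE(is_repeat))
  )
  filter_report(contig_id, "prior_filter", reasons)
}
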