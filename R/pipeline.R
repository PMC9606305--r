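#' Pipeline configuration with published defaults
#'
#' Aggregates every stage threshold: 100 kbp length, 100 markers, 20 tRNA
#' types and all three rRNAs (prior filter); ANI > 0.99 with coverage >
#' 0.95 (redundancy); ANI > 0.95 with coverage > 0.8, the Collinsella 0.94
#' override and the 100-genome cap (conspecific search); core contigs >
#' 5 kbp present in > 80% of other members; retrieval rate >= 0.95 with >=
#' 5 conspecific genomes (congruency); coverage > 0.6 for isolate-derived
#' conspecifics; 1 kbp / 10 bp GC-skew windows; and <= 20% over > 5
#' consecutive 1-kbp bins for low-retrieval segments.
#'
#' @param ... Named overrides of any default listed above.
#' @param seed RNG seed recorded in the config.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- list(
    min_length_bp = 100000, min_marker_count = 100,
    required_rrna_types = c("5S", "16S", "23S"), min_trna_types = 20,
    rrna_mode = "all",
    derep_ani = 0.99, derep_cov = 0.95,
    conspecific_ani = 0.95, conspecific_cov = 0.8,
    genus_ani_overrides = c(Collinsella = 0.94), conspecific_cap = 100,
    core_min_len = 5000, core_presence = 0.8, presence_identity = 0.95,
    retrieval_threshold = 0.95, min_conspecific = 5,
    isolate_cov = 0.6,
    skew_window = 1000, skew_step = 10,
    bin_size = 1000, low_rate = 20, low_min_bins = 5,
    run_metrics = TRUE, seed = seed
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  frac <- c("derep_ani", "derep_cov", "conspecific_ani", "conspecific_cov",
            "core_presence", "presence_identity", "retrieval_threshold",
            "isolate_cov")
  for (f in frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config field '", f, "' must be a fraction in [0, 1]; got ",
           cfg[[f]])
    }
  }
  stopifnot(cfg$min_length_bp > 0, cfg$min_marker_count > 0,
            cfg$min_trna_types > 0, cfg$min_conspecific >= 1,
            cfg$conspecific_cap >= 1, cfg$bin_size >= 1,
            cfg$skew_window >= 1, cfg$skew_step >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genus_ani_overrides)) {
    raw$genus_ani_overrides <- unlist(raw$genus_ani_overrides)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$genus_ani_overrides <- as.list(x$genus_ani_overrides)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full cMAG selection workflow
#'
#' Stages in order: assembly-graph screen (bubbles, repeats), biological
#' prior filter, redundancy removal, conspecific congruency filtering, and
#' post-acceptance metrics (GC skew, bin retrieval). Each stage's survivors
#' are recorded; re-running with an identical config and inputs reproduces
#' identical reports.
#'
#' @param contigs Circular contig set ([contig_set()]).
#' @param annotations Named list of [annotation_set()] per contig.
#' @param catalog A [genome_catalog()] of conspecific reference genomes.
#' @param genus_map Named character vector: contig id -> genus.
#' @param graph Optional [assembly_graph()] for bubble detection.
#' @param repeat_ids Character vector of contig ids flagged as repeats.
#' @param config A [pipeline_config()].
#' @return List of class `cmag_run`: `accepted` (contig set),
#'   `prior_reports`, `clusters`, `decisions`, `culturability`, `metrics`,
#'   `summary` (per-contig stage outcomes).
#' @export
run_all <- function(contigs, annotations = list(), catalog = NULL,
                    genus_map = character(), graph = NULL,
                    repeat_ids = character(),
                    config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  empty_run <- structure(list(accepted = NULL, prior_reports = list(),
                              clusters = NULL, decisions = list(),
                              culturability = list(), metrics = list(),
                              summary = data.frame()),
                         class = "cmag_run")
  if (length(contigs) == 0) {
    warning("empty input: no circular contigs to evaluate")
    return(empty_run)
  }

  bubble_segs <- if (!is.null(graph)) detect_bubbles(graph) else character(0)

  thr <- prior_thresholds(config$min_length_bp, config$min_marker_count,
                          config$required_rrna_types, config$min_trna_types,
                          config$rrna_mode)
  circ <- S4Vectors::mcols(contigs)$circular
  if (is.null(circ)) circ <- rep(TRUE, length(contigs))
  prior_reports <- lapply(seq_along(contigs), function(i) {
    id <- names(contigs)[i]
    apply_prior_filter(id, Biostrings::width(contigs)[i],
                       circular = circ[i],
                       annotation = annotations[[id]],
                       in_bubble = id %in% bubble_segs,
                       is_repeat = id %in% repeat_ids,
                       thresholds = thr)
  })
  names(prior_reports) <- names(contigs)
  survivors <- names(contigs)[vapply(prior_reports, `[[`, TRUE, "passed")]

  clusters <- NULL
  reps <- survivors
  if (length(survivors) >= 2) {
    dr <- dereplicate(contigs[survivors], config$derep_ani,
                      config$derep_cov)
    clusters <- dr$clusters
    reps <- dr$representatives
  }

  decisions <- list()
  cultur <- list()
  core_cache <- list()
  member_cache <- list()
  if (!is.null(catalog)) {
    for (id in reps) {
      decisions[[id]] <- tryCatch({
        genus <- genus_map[[id]]
        if (is.null(genus) || is.na(genus)) {
          stop("no genus annotation for contig")
        }
        q <- stats::setNames(as.character(contigs[[id]]), id)
        cs <- find_conspecific(q, catalog, genus,
                               conspecific_ani = config$conspecific_ani,
                               cov_threshold = config$conspecific_cov,
                               genus_ani_overrides =
                                 config$genus_ani_overrides,
                               cap = config$conspecific_cap)
        n_cons <- nrow(cs$members)
        if (n_cons < config$min_conspecific) {
          structure(list(query_id = id, retrieval_rate = NA_real_,
                         n_core = 0L, n_retrieved = 0L,
                         n_conspecific = n_cons,
                         verdict = "reject_few_conspecific",
                         per_contig = logical(0)),
                    class = "congruency_decision")
        } else {
          key <- paste(cs$species_cluster_id,
                       paste(sort(cs$members$genome_id), collapse = "|"))
          if (is.null(core_cache[[key]])) {
            core_cache[[key]] <- identify_core_contigs(
              catalog$genomes[cs$members$genome_id],
              min_len = config$core_min_len,
              presence_threshold = config$core_presence,
              min_identity = config$presence_identity)
          }
          member_cache[[id]] <- catalog$genomes[cs$members$genome_id]
          core_retrieval_rate(q, core_cache[[key]], n_cons,
                              min_rate = config$retrieval_threshold,
                              min_conspecific = config$min_conspecific,
                              min_identity = config$presence_identity)
        }
      }, error = function(e) {
        stop("congruency stage failed for contig '", id, "': ",
             conditionMessage(e), call. = FALSE)
      })
      cultur[[id]] <- culturability(
        stats::setNames(as.character(contigs[[id]]), id), catalog,
        ani_threshold = config$conspecific_ani,
        cov_threshold = config$isolate_cov)
    }
  }

  accepted_ids <- names(decisions)[vapply(decisions, `[[`, "", "verdict") ==
                                     "accept"]
  if (is.null(catalog)) accepted_ids <- reps

  metrics <- list()
  if (config$run_metrics) {
    for (id in accepted_ids) {
      q <- stats::setNames(as.character(contigs[[id]]), id)
      m <- list(gc_skew = gc_skew(q, window = config$skew_window,
                                  step = config$skew_step,
                                  circular = circ[match(id,
                                                        names(contigs))]))
      if (!is.null(member_cache[[id]])) {
        m$retrieval <- bin_retrieval(q, member_cache[[id]],
                                     bin_size = config$bin_size,
                                     low_rate = config$low_rate,
                                     low_min_bins = config$low_min_bins)
      }
      metrics[[id]] <- m
    }
  }

  summary <- data.frame(
    contig_id = names(contigs),
    prior_pass = names(contigs) %in% survivors,
    representative = names(contigs) %in% reps,
    verdict = vapply(names(contigs), function(id) {
      if (!is.null(decisions[[id]])) decisions[[id]]$verdict
      else if (id %in% reps) "not_evaluated"
      else if (id %in% survivors) "redundant"
      else "prior_fail"
    }, ""),
    row.names = NULL
  )

  structure(list(accepted = contigs[accepted_ids],
                 prior_reports = prior_reports, clusters = clusters,
                 decisions = decisions, culturability = cultur,
                 metrics = metrics, summary = summary),
            class = "cmag_run")
}

#' @export
print.cmag_run <- function(x, ...) {
  cat("cMAG selection run:", nrow(x$summary), "input contig(s),",
      length(x$accepted), "accepted\n")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
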