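# Synthetic species pangenomes with recorded ground truth. Mutations are
# uniform i.i.d. (no selection or recombination model): enough to exercise
# every threshold of the selection workflow.

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @return A character scalar over ACGT drawn from the current RNG stream.
#' @export
random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

#' Mutate a sequence with Poisson-planted substitutions and indels
#'
#' @param sequence Character scalar.
#' @param snv_rate,indel_rate Per-base event rates.
#' @param max_indel Maximum indel length (default 10).
#' @return List with `sequence` and `truth` (data frame `pos` in original
#'   0-based coordinates, `type` of sub/ins/del, `detail`).
#' @export
mutate_sequence <- function(sequence, snv_rate, indel_rate = 0,
                            max_indel = 10) {
  r <- charToRaw(sequence)
  L <- length(r)
  alphabet <- as.raw(c(65L, 67L, 71L, 84L)) # A C G T
  truth <- list()

  n_sub <- rpois(1, L * snv_rate)
  if (n_sub > 0) {
    pos <- sort(sample.int(L, min(n_sub, L)))
    code <- match(r[pos], alphabet)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    r[pos] <- alphabet[((code - 1L + shift) %% 4L) + 1L]
    truth[[length(truth) + 1L]] <-
      data.frame(pos = pos - 1L, type = "sub",
                 detail = rawToChar(r[pos]) |>
                   strsplit("") |> unlist())
  }

  n_ind <- rpois(1, L * indel_rate)
  if (n_ind > 0) {
    pos <- sort(sample.int(L - max_indel, min(n_ind, L - max_indel)),
                decreasing = TRUE)
    kinds <- sample(c("ins", "del"), length(pos), replace = TRUE)
    lens <- sample.int(max_indel, length(pos), replace = TRUE)
    for (i in seq_along(pos)) {
      p <- pos[i]
      if (kinds[i] == "del") {
        r <- r[-(p:(p + lens[i] - 1L))]
      } else {
        r <- append(r, charToRaw(random_dna(lens[i])), after = p)
      }
    }
    truth[[length(truth) + 1L]] <-
      data.frame(pos = pos - 1L, type = kinds,
                 detail = as.character(lens))
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(pos = integer(), type = character(), detail = character())
  list(sequence = rawToChar(r), truth = truth)
}

#' Simulate a species: an ancestor plus mutated genome copies
#'
#' The ancestor is drawn uniformly over ACGT; each genome is the ancestor
#' with Poisson-planted substitutions and indels. Reproducible bit-for-bit
#' from (parameters, seed).
#'
#' @param ancestor_len Ancestor length (>= 200 kbp recommended for
#'   pipeline-scale tests; smaller lengths are fine for unit tests).
#' @param n_genomes Number of genome copies.
#' @param snv_rate,indel_rate Per-base event rates, each in \[0, 0.05\].
#' @param seed RNG seed.
#' @return List of class `synthetic_species`: `ancestor`, `genomes` (named
#'   character vector), `truth` (per-genome planted events), `seed`.
#' @export
make_species <- function(ancestor_len, n_genomes, snv_rate,
                         indel_rate = 0, seed = 1) {
  if (snv_rate < 0 || snv_rate > 0.05 || indel_rate < 0 ||
      indel_rate > 0.05) {
    stop("snv_rate and indel_rate must lie in [0, 0.05]")
  }
  set.seed(seed)
  ancestor <- random_dna(ancestor_len)
  genomes <- character(n_genomes)
  truth <- vector("list", n_genomes)
  ids <- sprintf("G%02d", seq_len(n_genomes))
  for (i in seq_len(n_genomes)) {
    m <- mutate_sequence(ancestor, snv_rate, indel_rate)
    genomes[i] <- m$sequence
    truth[[i]] <- m$truth
  }
  names(genomes) <- ids
  names(truth) <- ids
  structure(list(ancestor = ancestor, genomes = genomes, truth = truth,
                 snv_rate = snv_rate, indel_rate = indel_rate, seed = seed),
            class = "synthetic_species")
}

#' Fragment a genome into a MAG-like multi-contig assembly
#'
#' Breakpoints follow exponential spacing around `mean_contig_len`; a
#' `dropout_fraction` of the resulting contigs is removed, emulating MAG
#' gaps. At least one contig always survives.
#'
#' @param genome Character scalar.
#' @param mean_contig_len Mean fragment length in bp.
#' @param dropout_fraction Per-contig removal probability.
#' @param prefix Contig name prefix.
#' @return List with `contigs` (named character vector) and `truth`
#'   (data frame `contig_id`, `start`, `end`, `kept`).
#' @export
fragment_into_mags <- function(genome, mean_contig_len,
                               dropout_fraction = 0, prefix = "c") {
  L <- nchar(genome)
  cuts <- integer(0)
  pos <- 0
  while (pos < L) {
    len <- max(500, round(rexp(1, rate = 1 / mean_contig_len)))
    pos <- pos + len
    if (pos < L) cuts <- c(cuts, pos)
  }
  starts <- c(0L, cuts)
  ends <- c(cuts, L)
  ids <- sprintf("%s%03d", prefix, seq_along(starts))
  kept <- runif(length(starts)) >= dropout_fraction
  if (!any(kept)) kept[1] <- TRUE
  contigs <- substring(genome, starts + 1L, ends)
  names(contigs) <- ids
  list(contigs = contigs[kept],
       truth = data.frame(contig_id = ids, start = starts, end = ends,
                          kept = kept))
}

#' Plant deletions and foreign-island insertions into a genome
#'
#' Deletions excise the given spans (0-based half-open, non-overlapping);
#' islands are then inserted at sites interpreted in the post-deletion
#' coordinate system. Island sequences are drawn from an independent random
#' stream, guaranteeing non-homology with the species.
#'
#' @param genome Character scalar.
#' @param deletion_spans Data frame with `start`, `end`, or NULL.
#' @param island_inserts Data frame with `site`, `length`, or NULL.
#' @return List with `sequence` and `truth` (`deletions`, `islands` with
#'   inserted sequences and final coordinates).
#' @export
plant_defect <- function(genome, deletion_spans = NULL,
                         island_inserts = NULL) {
  s <- genome
  del_truth <- NULL
  if (!is.null(deletion_spans) && nrow(deletion_spans)) {
    d <- deletion_spans[order(deletion_spans$start), , drop = FALSE]
    stopifnot(all(d$start < d$end), all(d$end <= nchar(genome)))
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping deletion spans")
    }
    for (i in rev(seq_len(nrow(d)))) {
      s <- paste0(substr(s, 1, d$start[i]),
                  substring(s, d$end[i] + 1L))
    }
    del_truth <- d
  }
  isl_truth <- NULL
  if (!is.null(island_inserts) && nrow(island_inserts)) {
    ii <- island_inserts[order(island_inserts$site, decreasing = TRUE), ,
                         drop = FALSE]
    stopifnot(all(ii$site <= nchar(s)), all(ii$length > 0))
    seqs <- character(nrow(ii))
    for (i in seq_len(nrow(ii))) {
      seqs[i] <- random_dna(ii$length[i])
      s <- paste0(substr(s, 1, ii$site[i]), seqs[i],
                  substring(s, ii$site[i] + 1L))
    }
    isl_truth <- data.frame(site = ii$site, length = ii$length,
                            sequence = seqs)
  }
  list(sequence = s, truth = list(deletions = del_truth,
                                  islands = isl_truth))
}

#' Full synthetic study fixture: one species, fragmented MAGs, three queries
#'
#' Builds the end-to-end test bed: a 500 kbp species with 10 conspecific
#' MAG-like catalog genomes (0.5% substitutions, sparse short indels,
#' ~50 kbp fragments, 5% contig dropout), a complete circular query, a
#' defective query carrying one large deletion, and a near-duplicate of the
#' complete query for the redundancy stage. Prior-filter annotations that
#' pass all thresholds are synthesized for the queries, so the pipeline
#' stages under study are dereplication and congruency.
#'
#' @param seed RNG seed.
#' @param ancestor_len Species ancestor length (default 500000).
#' @param n_mags Number of catalog MAGs (default 10).
#' @param snv_rate Member divergence from the ancestor (default 0.005).
#' @param indel_rate Member indel rate (default 1e-4).
#' @param mean_contig_len MAG fragment length (default 50000).
#' @param dropout MAG contig dropout fraction (default 0.05).
#' @param deletion_frac Deleted fraction of the defective query
#'   (default 0.2).
#' @param genus Genus label shared by catalog and queries.
#' @return List: `queries` (contig set with `complete`, `gapped`,
#'   `duplicate`), `catalog`, `annotations`, `genus_map`, `members`
#'   (named list of MAG sequence sets), `truth`.
#' @export
make_pipeline_fixture <- function(seed, ancestor_len = 500000, n_mags = 10,
                                  snv_rate = 0.005, indel_rate = 1e-4,
                                  mean_contig_len = 50000, dropout = 0.05,
                                  deletion_frac = 0.2,
                                  genus = "Synthetica") {
  sp <- make_species(ancestor_len, n_mags, snv_rate, indel_rate, seed = seed)
  mags <- lapply(sp$genomes, fragment_into_mags,
                 mean_contig_len = mean_contig_len,
                 dropout_fraction = dropout)
  members <- lapply(mags, `[[`, "contigs")
  names(members) <- names(sp$genomes)

  complete <- mutate_sequence(sp$ancestor, snv_rate, indel_rate)$sequence
  gapped_base <- mutate_sequence(sp$ancestor, 0.008, indel_rate)$sequence
  del_len <- round(deletion_frac * nchar(gapped_base))
  del_start <- sample.int(nchar(gapped_base) - del_len, 1)
  gapped <- plant_defect(gapped_base,
                         deletion_spans = data.frame(start = del_start,
                                                     end = del_start +
                                                       del_len))
  duplicate <- mutate_sequence(complete, 0.002)$sequence

  queries <- contig_set(c(complete = complete,
                          gapped = gapped$sequence,
                          duplicate = duplicate),
                        circular = TRUE)

  meta <- data.frame(
    genome_id = names(members),
    species_cluster_id = "SC1",
    genus = genus,
    is_representative = seq_along(members) == 1L,
    is_isolate = seq_along(members) == 1L,
    is_complete = FALSE
  )
  catalog <- genome_catalog(members, meta)

  annotations <- lapply(names(queries), function(id) {
    annotation_set(
      id,
      marker_ids = sprintf("bac120_m%03d", 1:120),
      rrna = data.frame(contig_id = id, type = c("5S", "16S", "23S"),
                        start = c(100L, 400L, 2200L),
                        end = c(220L, 1950L, 5100L), strand = "+"),
      trna = data.frame(contig_id = id,
                        isotype = sprintf("iso%02d", 1:21),
                        pseudo = FALSE,
                        start = 100L * (1:21), end = 100L * (1:21) + 75L)
    )
  })
  names(annotations) <- names(queries)

  genus_map <- stats::setNames(rep(genus, length(queries)), names(queries))

  list(queries = queries, catalog = catalog, annotations = annotations,
       genus_map = genus_map, members = members,
       truth = list(seed = seed, species = sp,
                    deletion = gapped$truth$deletions,
                    mags = lapply(mags, `[[`, "truth")))
}
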