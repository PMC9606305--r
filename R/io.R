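#' Read circular/linear contigs from a FASTA file
#'
#' Sequences are uppercased and validated against the \{A,C,G,T,N\} alphabet.
#' Circularity is taken from a `circular=true` / `circular=false` token in the
#' FASTA header if present, otherwise `FALSE`. The first whitespace-delimited
#' word of the header is the contig id.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id, with metadata
#'   column `circular` (logical).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  circ <- grepl("circular=true", headers, ignore.case = TRUE)
  contig_set(toupper(as.character(seqs)), ids = ids, circular = circ)
}

#' Construct a contig set
#'
#' @param sequences Character vector of DNA sequences (or a DNAStringSet).
#' @param ids Contig identifiers; defaults to names of `sequences`.
#' @param circular Logical vector, recycled to length.
#' @return A DNAStringSet with a `circular` metadata column.
#' @export
contig_set <- function(sequences, ids = names(sequences), circular = FALSE) {
  force(ids)
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) stop("contig ids are required")
  if (anyDuplicated(ids)) stop("contig ids must be unique")
  if (any(nchar(sequences) < 1L)) stop("empty sequence not allowed")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence alphabet outside {A,C,G,T,N} in contig(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(sequences)
  names(out) <- ids
  S4Vectors::mcols(out)$circular <- rep_len(as.logical(circular), length(out))
  out
}

#' Write contigs to FASTA, preserving circularity in the header
#'
#' @param contigs A DNAStringSet as returned by [read_fasta()]/[contig_set()].
#' @param path Output path.
#' @export
write_fasta <- function(contigs, path) {
  circ <- S4Vectors::mcols(contigs)$circular
  if (is.null(circ)) circ <- rep(FALSE, length(contigs))
  out <- contigs
  names(out) <- paste0(names(contigs), " circular=",
                       ifelse(circ, "true", "false"))
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}

is_circular <- function(contigs, id) {
  circ <- S4Vectors::mcols(contigs)$circular
  if (is.null(circ)) return(FALSE)
  isTRUE(circ[match(id, names(contigs))])
}

#' Read marker, rRNA and tRNA annotations for a contig collection
#'
#' Marker table: TSV with columns `contig_id`, `marker_id` (bac120/arc122
#' namespaces). rRNA file: GFF3 whose type/attributes name 5S, 16S or 23S.
#' tRNA table: TSV with columns `contig_id`, `isotype`, `pseudo`, `start`,
#' `end` (0-based half-open). Pseudo tRNAs are retained here; downstream
#' filters decide whether to count them. Any argument may be `NULL`, yielding
#' empty components.
#'
#' @param marker_table_path,rrna_gff_path,trna_table_path Input paths (or
#'   `NULL`).
#' @param contig_lengths Optional named integer vector; when given, feature
#'   coordinates are validated against it.
#' @return Named list of annotation sets, one per contig mentioned in any
#'   input; each has `marker_ids` (character), `rrna` and `trna` data frames.
#' @export
read_annotations <- function(marker_table_path = NULL, rrna_gff_path = NULL,
                             trna_table_path = NULL, contig_lengths = NULL) {
  markers <- if (!is.null(marker_table_path)) {
    m <- read.delim(marker_table_path, header = TRUE,
                    colClasses = "character")
    stopifnot(all(c("contig_id", "marker_id") %in% names(m)))
    m
  } else {
    data.frame(contig_id = character(), marker_id = character())
  }
  rrna <- if (!is.null(rrna_gff_path)) {
    read_rrna_gff3(rrna_gff_path)
  } else {
    empty_rrna()
  }
  trna <- if (!is.null(trna_table_path)) {
    t <- read.delim(trna_table_path, header = TRUE)
    stopifnot(all(c("contig_id", "isotype", "pseudo", "start", "end")
                  %in% names(t)))
    t$pseudo <- parse_bool(t$pseudo)
    t
  } else {
    data.frame(contig_id = character(), isotype = character(),
               pseudo = logical(), start = integer(), end = integer())
  }

  if (!is.null(contig_lengths)) {
    check_coords <- function(df, what) {
      ok <- df$contig_id %in% names(contig_lengths)
      len <- contig_lengths[df$contig_id[ok]]
      bad <- df$start[ok] < 0 | df$end[ok] > len | df$start[ok] >= df$end[ok]
      if (any(bad)) {
        stop("coordinates outside contig bounds in ", what, " record(s): ",
             paste(utils::head(which(ok)[bad], 5), collapse = ", "))
      }
    }
    check_coords(rrna, "rRNA")
    check_coords(trna, "tRNA")
  }

  ids <- unique(c(markers$contig_id, rrna$contig_id, trna$contig_id))
  out <- lapply(ids, function(id) {
    annotation_set(
      contig_id = id,
      marker_ids = unique(markers$marker_id[markers$contig_id == id]),
      rrna = rrna[rrna$contig_id == id, , drop = FALSE],
      trna = trna[trna$contig_id == id, , drop = FALSE]
    )
  })
  names(out) <- ids
  out
}

#' Build an annotation set for one contig
#'
#' @param contig_id Contig identifier.
#' @param marker_ids Character vector of single-copy marker ids (deduplicated).
#' @param rrna Data frame with `type` (5S/16S/23S), `start`, `end`, `strand`.
#' @param trna Data frame with `isotype`, `pseudo`, `start`, `end`.
#' @export
annotation_set <- function(contig_id, marker_ids = character(),
                           rrna = empty_rrna(), trna = NULL) {
  if (is.null(trna)) {
    trna <- data.frame(contig_id = character(), isotype = character(),
                       pseudo = logical(), start = integer(), end = integer())
  }
  if (nrow(rrna) && !all(rrna$type %in% c("5S", "16S", "23S"))) {
    stop("rRNA type must be one of 5S/16S/23S")
  }
  structure(list(contig_id = contig_id,
                 marker_ids = unique(as.character(marker_ids)),
                 rrna = rrna, trna = trna),
            class = "annotation_set")
}

#' Empty rRNA interval table (the [annotation_set()] default)
#' @export
empty_rrna <- function() {
  data.frame(contig_id = character(), type = character(),
             start = integer(), end = integer(), strand = character())
}

parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop("malformed boolean value(s): ",
         paste(unique(v[is.na(out)]), collapse = ", "))
  }
  out
}

# GFF3 rRNA reader; converts 1-based closed coordinates to 0-based half-open.
read_rrna_gff3 <- function(path) {
  gr <- if (requireNamespace("rtracklayer", quietly = TRUE)) {
    rtracklayer::import(path, format = "gff3")
  } else {
    gff3_fallback(path)
  }
  df <- as.data.frame(gr)
  label <- paste(df$type,
                 if ("Name" %in% names(df)) df$Name else "",
                 if ("product" %in% names(df)) df$product else "")
  kind <- rep(NA_character_, nrow(df))
  kind[grepl("23S", label)] <- "23S"
  kind[grepl("16S", label)] <- "16S"
  kind[grepl("5S", label) & is.na(kind)] <- "5S"
  keep <- !is.na(kind)
  data.frame(contig_id = as.character(df$seqnames)[keep],
             type = kind[keep],
             start = df$start[keep] - 1L,   # to 0-based half-open
             end = df$end[keep],
             strand = as.character(df$strand)[keep])
}

# minimal GFF3 reader used only when rtracklayer is unavailable
gff3_fallback <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- strsplit(ln, "\t")
  df <- data.frame(
    seqnames = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7)
  )
  attr9 <- vapply(f, `[`, "", 9)
  df$Name <- sub(".*Name=([^;]+).*", "\\1", attr9)
  df$Name[!grepl("Name=", attr9)] <- ""
  df
}

#' Read feature intervals (rRNA, genomic islands) from GFF3 or BED
#'
#' Returns 0-based half-open intervals with a `kind` column. For GFF3, the
#' kind is taken from the type column / Name attribute (rRNA5S, rRNA16S,
#' rRNA23S, genomic_island); BED uses the name field directly.
#'
#' @param path Input path.
#' @param format `"gff3"` or `"bed"` (guessed from extension by default).
#' @export
read_feature_intervals <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    b <- read.delim(path, header = FALSE)
    df <- data.frame(contig_id = as.character(b[[1]]),
                     kind = as.character(b[[4]]),
                     start = as.integer(b[[2]]), end = as.integer(b[[3]]))
  } else {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    f <- strsplit(ln, "\t")
    attr9 <- vapply(f, function(x) if (length(x) >= 9) x[9] else "", "")
    kind <- vapply(f, `[`, "", 3)
    named <- grepl("Name=", attr9)
    kind[named] <- sub(".*Name=([^;]+).*", "\\1", attr9[named])
    df <- data.frame(contig_id = vapply(f, `[`, "", 1),
                     kind = kind,
                     start = as.integer(vapply(f, `[`, "", 4)) - 1L,
                     end = as.integer(vapply(f, `[`, "", 5)))
  }
  stopifnot(all(df$start < df$end))
  df
}

#' Write feature intervals as GFF3 (1-based closed on disk)
#'
#' @param features Data frame with `contig_id`, `kind`, `start`, `end`
#'   (0-based half-open).
#' @param path Output path.
#' @export
write_feature_intervals <- function(features, path) {
  ln <- sprintf("%s\tcmagkit\t%s\t%d\t%d\t.\t+\t.\tName=%s",
                features$contig_id, features$kind,
                features$start + 1L, features$end, features$kind)
  writeLines(c("##gff-version 3", ln), path)
  invisible(path)
}

#' Create a per-contig filter report
#'
#' @param contig_id Contig id.
#' @param stage Pipeline stage name.
#' @param reasons Data frame with columns `criterion`, `observed`,
#'   `threshold`, `passed` — one row per evaluated criterion.
#' @return A `filter_report`; `passed` is TRUE iff no criterion failed.
#' @export
filter_report <- function(contig_id, stage, reasons) {
  stopifnot(all(c("criterion", "observed", "threshold", "passed")
                %in% names(reasons)))
  structure(list(contig_id = contig_id, stage = stage,
                 passed = all(reasons$passed),
                 reasons = reasons),
            class = "filter_report")
}

#' Write filter reports as TSV plus a machine-readable JSON twin
#'
#' The TSV has one row per (contig, stage) with failed criteria collapsed
#' into a `reason` field; the JSON file (same path with `.json` appended to
#' the stem) round-trips the full report structure.
#'
#' @param reports List of [filter_report()] objects.
#' @param path Output TSV path.
#' @export
write_report <- function(reports, path) {
  stopifnot(length(reports) > 0)
  rows <- do.call(rbind, lapply(reports, function(r) {
    fail <- r$reasons[!r$reasons$passed, , drop = FALSE]
    reason <- paste(sprintf("%s(observed=%s,threshold=%s)", fail$criterion,
                            fail$observed, fail$threshold), collapse = ";")
    data.frame(contig_id = r$contig_id, stage = r$stage,
               status = if (r$passed) "PASS" else "FAIL",
               reason = reason)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- paste0(sub("\\.tsv$", "", path), ".json")
  payload <- lapply(reports, function(r) {
    list(contig_id = r$contig_id, stage = r$stage, passed = r$passed,
         reasons = r$reasons)
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-read the JSON twin written by [write_report()]
#'
#' @param json_path Path to the JSON report.
#' @return List of `filter_report` objects.
#' @export
read_report_json <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    reasons <- do.call(rbind, lapply(r$reasons, function(x) {
      data.frame(criterion = x$criterion,
                 observed = as.character(x$observed),
                 threshold = as.character(x$threshold),
                 passed = x$passed)
    }))
    filter_report(r$contig_id, r$stage, reasons)
  })
}

#' Read a conspecific genome catalog
#'
#' @param meta_path TSV with columns `genome_id`, `species_cluster_id`,
#'   `genus`, `is_representative`, `is_isolate`, `is_complete`.
#' @param fasta_dir Directory containing `<genome_id>.fasta` files.
#' @return A [genome_catalog()].
#' @export
read_catalog <- function(meta_path, fasta_dir) {
  meta <- read.delim(meta_path, header = TRUE, colClasses = "character")
  for (col in c("is_representative", "is_isolate", "is_complete")) {
    meta[[col]] <- parse_bool(meta[[col]])
  }
  genomes <- lapply(meta$genome_id, function(g) {
    read_fasta(file.path(fasta_dir, paste0(g, ".fasta")))
  })
  names(genomes) <- meta$genome_id
  genome_catalog(genomes, meta)
}

#' Construct a genome catalog of conspecific reference genomes
#'
#' @param genomes Named list of DNAStringSet, one per genome.
#' @param metadata Data frame with `genome_id`, `species_cluster_id`,
#'   `genus`, `is_representative`, `is_isolate`, `is_complete`. Exactly one
#'   representative per species cluster is required.
#' @export
genome_catalog <- function(genomes, metadata) {
  need <- c("genome_id", "species_cluster_id", "genus",
            "is_representative", "is_isolate", "is_complete")
  stopifnot(all(need %in% names(metadata)))
  if (anyDuplicated(metadata$genome_id)) {
    stop("duplicate genome_id in catalog metadata")
  }
  if (!setequal(names(genomes), metadata$genome_id)) {
    stop("catalog sequences and metadata name different genomes")
  }
  reps <- tapply(metadata$is_representative, metadata$species_cluster_id, sum)
  if (any(reps != 1L)) {
    stop("each species cluster needs exactly one representative; offending: ",
         paste(names(reps)[reps != 1L], collapse = ", "))
  }
  structure(list(genomes = genomes,
                 metadata = metadata[, need]),
            class = "genome_catalog")
}

#' @export
print.genome_catalog <- function(x, ...) {
  cat("genome_catalog:", length(x$genomes), "genomes,",
      length(unique(x$metadata$species_cluster_id)), "species clusters\n")
  invisible(x)
}

#' Export alignment blocks as PAF
#'
#' Standard PAF columns (0-based half-open) with an `NM:i:` substitution tag,
#' so externally produced alignments can be injected at any stage.
#'
#' @param blocks Block data frame from [align()].
#' @param path Output path.
#' @param ref_lengths,qry_lengths Named integer vectors of contig lengths.
#' @export
write_paf <- function(blocks, path, ref_lengths, qry_lengths) {
  ln <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255\tNM:i:%d",
                blocks$qry_contig, qry_lengths[blocks$qry_contig],
                blocks$qry_start, blocks$qry_end, blocks$strand,
                blocks$ref_contig, ref_lengths[blocks$ref_contig],
                blocks$ref_start, blocks$ref_end,
                as.integer(blocks$matches), as.integer(blocks$aligned_length),
                as.integer(blocks$mismatches))
  writeLines(ln, path)
  invisible(path)
}

#' Read alignment blocks from PAF written by [write_paf()]
#'
#' @param path PAF path.
#' @export
read_paf <- function(path) {
  f <- strsplit(readLines(path), "\t")
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:12)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  blocks <- data.frame(
    ref_contig = vapply(f, `[`, "", 6),
    qry_contig = vapply(f, `[`, "", 1),
    ref_start = as.integer(vapply(f, `[`, "", 8)),
    ref_end = as.integer(vapply(f, `[`, "", 9)),
    qry_start = as.integer(vapply(f, `[`, "", 3)),
    qry_end = as.integer(vapply(f, `[`, "", 4)),
    strand = vapply(f, `[`, "", 5),
    matches = as.numeric(vapply(f, `[`, "", 10)),
    mismatches = as.numeric(nm),
    aligned_length = as.numeric(vapply(f, `[`, "", 11))
  )
  blocks$identity <- ifelse(blocks$aligned_length > 0,
                            blocks$matches / blocks$aligned_length, 0)
  blocks
}
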