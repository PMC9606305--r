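#' Windowed GC-skew profile with origin/terminus diagnostics
#'
#' Computes (G - C) / (G + C) in sliding windows (defaults 1 kbp window,
#' 10 bp slide), the cumulative skew curve, and the positions of its
#' minimum (replication origin candidate) and maximum (terminus candidate).
#' Circular contigs are traversed with wraparound so every position is
#' covered. N bases are ignored in the counts; an all-AT window has skew 0.
#' A symmetry score (Pearson correlation of the ascending arm against the
#' reflected descending arm of the cumulative curve) and a smoothed peak
#' count are emitted as quantitative diagnostics in place of manual pattern
#' classes.
#'
#' @param contig Single sequence (named character or DNAStringSet of one).
#' @param window,step Window and slide in bp (defaults 1000 and 10).
#' @param circular Traverse with wraparound? Defaults to the `circular`
#'   metadata column when `contig` is a DNAStringSet, else FALSE.
#' @return List of class `skew_profile`: `starts` (0-based window starts),
#'   `skew`, `cumulative`, `ori_pos`, `ter_pos`, `symmetry`, `n_peaks`.
#' @export
gc_skew <- function(contig, window = 1000, step = 10, circular = NULL) {
  if (is.null(circular) && methods::is(contig, "DNAStringSet")) {
    circ_col <- S4Vectors::mcols(contig)$circular
    circular <- if (!is.null(circ_col)) isTRUE(circ_col[1]) else FALSE
  }
  if (is.null(circular)) circular <- FALSE
  s <- as_seq_chr(contig, "contig")[[1]]
  L <- nchar(s)
  if (L < window) stop("contig shorter than the skew window (", window, ")")
  ext <- if (circular) paste0(s, substr(s, 1, window - 1)) else s
  r <- charToRaw(ext)
  cg <- c(0, cumsum(r == charToRaw("G")))
  cc <- c(0, cumsum(r == charToRaw("C")))
  starts <- if (circular) {
    seq(0L, L - 1L, by = step)
  } else {
    seq(0L, L - window, by = step)
  }
  g <- cg[starts + window + 1L] - cg[starts + 1L]
  c_ <- cc[starts + window + 1L] - cc[starts + 1L]
  denom <- g + c_
  skew <- ifelse(denom > 0, (g - c_) / denom, 0)
  cum <- cumsum(skew)
  i_ori <- which.min(cum)
  i_ter <- which.max(cum)

  n <- length(cum)
  circ_slice <- function(i, j) {
    if (i <= j) cum[i:j] else cum[c(i:n, 1:j)]
  }
  symmetry <- NA_real_
  if (i_ori != i_ter && n >= 4) {
    a1 <- circ_slice(i_ori, i_ter)   # ascending arm
    a2 <- circ_slice(i_ter, i_ori)   # descending arm
    if (length(a1) >= 3 && length(a2) >= 3) {
      m <- 200
      r1 <- approx(seq_along(a1), a1, n = m)$y
      r2 <- approx(seq_along(a2), rev(a2), n = m)$y
      if (stats::sd(r1) > 0 && stats::sd(r2) > 0) {
        symmetry <- cor(r1, r2)
      }
    }
  }
  kw <- min(25L, max(1L, n %/% 4L))
  sm <- as.numeric(stats::filter(cum, rep(1 / kw, kw), sides = 2))
  sm <- sm[!is.na(sm)]
  n_peaks <- if (length(sm) > 2) {
    sum(diff(sign(diff(sm))) == -2, na.rm = TRUE)
  } else 0L

  structure(list(starts = starts, skew = skew, cumulative = cum,
                 ori_pos = starts[i_ori], ter_pos = starts[i_ter],
                 symmetry = symmetry, n_peaks = n_peaks,
                 window = window, step = step, circular = circular),
            class = "skew_profile")
}

#' Count SNVs between a query and a conspecific reference
#'
#' Substitution columns (both sides A/C/G/T, bases differing) within
#' best-bidirectional alignment blocks. Indel columns are excluded from the
#' count (the show-snps -I analogue); positions adjacent to indels are
#' retained. `aligned_bases` counts matched plus substituted columns, and is
#' the density denominator, making densities commensurable across
#' conspecific genomes.
#'
#' @param query,reference Sequence sets.
#' @return List of class `snv_profile`: `snv_count`, `aligned_bases`,
#'   `snv_density`, `no_alignment` (flag).
#' @export
call_snvs <- function(query, reference) {
  blocks <- best_bidirectional(align(reference, query), axes = "both")
  count <- sum(blocks$mismatches)
  aligned <- sum(blocks$matches) + sum(blocks$mismatches)
  if (aligned == 0) {
    warning("no alignment between query and reference")
    return(structure(list(snv_count = 0L, aligned_bases = 0L,
                          snv_density = NA_real_, no_alignment = TRUE),
                     class = "snv_profile"))
  }
  structure(list(snv_count = as.integer(count),
                 aligned_bases = as.integer(aligned),
                 snv_density = count / aligned, no_alignment = FALSE),
            class = "snv_profile")
}

#' Percentile rank of a query SNV density among conspecific densities
#'
#' @param query_density SNV density of the query.
#' @param conspecific_densities Densities of the conspecific genomes; at
#'   least `min_n` are required for a reliable percentile (default 100,
#'   mirroring the published >100-genomes requirement).
#' @param min_n Minimum sample size.
#' @return Fraction of conspecific densities <= the query density (ties
#'   count).
#' @export
snv_percentile <- function(query_density, conspecific_densities,
                           min_n = 100) {
  if (length(conspecific_densities) < min_n) {
    stop("refusing to rank: only ", length(conspecific_densities),
         " conspecific densities (need >= ", min_n, ")")
  }
  mean(conspecific_densities <= query_density)
}

#' Genome-bin retrieval rate of a cMAG by its conspecific genomes
#'
#' Each conspecific genome is aligned to the cMAG, blocks are filtered for
#' the best alignment on the cMAG axis only, and per-position match columns
#' are accumulated. For a full bin B,
#' rate_B = sum over positions p in B of matched_count_p /
#' (bin_size x n_genomes) x 100 (%). A trailing partial bin is normalized
#' by its actual width by default (`partial = "fixed"` reproduces
#' unconditional division by `bin_size`). Low-retrieval segments are
#' maximal runs of bins at rate <= `low_rate` spanning more than
#' `low_min_bins` consecutive bins.
#'
#' @param cmag Single named cMAG sequence.
#' @param conspecific_genomes Named list of genome sequence sets.
#' @param bin_size Bin width in bp (default 1000).
#' @param partial `"width"` (default) or `"fixed"` trailing-bin
#'   normalization.
#' @param low_rate,low_min_bins Low-segment rule (20%, more than 5 bins).
#' @return List of class `retrieval_profile`: `bins` (data frame
#'   `bin_start`, `bin_end`, `rate`), `n_conspecific`, `low_segments`,
#'   `matched_counts`, `total_matched`.
#' @export
bin_retrieval <- function(cmag, conspecific_genomes, bin_size = 1000,
                          partial = c("width", "fixed"),
                          low_rate = 20, low_min_bins = 5) {
  partial <- match.arg(partial)
  cmag <- as_seq_chr(cmag, "cmag")
  stopifnot(length(cmag) == 1L, length(conspecific_genomes) >= 1L)
  L <- nchar(cmag)
  n <- length(conspecific_genomes)
  matched <- integer(L)
  if (is.null(names(conspecific_genomes))) {
    names(conspecific_genomes) <- sprintf("g%03d",
                                          seq_along(conspecific_genomes))
  }
  per_g <- align_per_genome(cmag, conspecific_genomes,
                            keep_match_pos = TRUE)
  for (blocks in per_g) {
    blocks <- best_bidirectional(blocks, axes = "ref")
    pos <- unique(unlist(blocks$match_pos))
    if (length(pos)) matched[pos + 1L] <- matched[pos + 1L] + 1L
  }
  starts <- seq(0L, L - 1L, by = bin_size)
  ends <- pmin(starts + bin_size, L)
  cm <- c(0, cumsum(matched))
  bin_sum <- cm[ends + 1L] - cm[starts + 1L]
  denom_w <- if (partial == "width") ends - starts else rep(bin_size,
                                                            length(starts))
  rate <- bin_sum / (denom_w * n) * 100

  low <- rate <= low_rate
  r <- rle(low)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  sel <- r$values & r$lengths > low_min_bins
  low_segments <- data.frame(start_bin = seg_start[sel],
                             end_bin = seg_end[sel],
                             start_bp = starts[seg_start[sel]],
                             end_bp = ends[seg_end[sel]])
  structure(list(bins = data.frame(bin_start = starts, bin_end = ends,
                                   rate = rate),
                 n_conspecific = n, low_segments = low_segments,
                 matched_counts = matched,
                 total_matched = sum(matched)),
            class = "retrieval_profile")
}

#' Compare retrieval rates of feature-bearing vs feature-free bins
#'
#' A bin "includes" a feature kind when any interval of that kind overlaps
#' it by at least 1 bp. Rates are compared by the two-sided Mann-Whitney U
#' test with normal approximation, tie correction and continuity correction
#' (stats::wilcox.test with exact = FALSE). Groups with fewer than 2 bins
#' are flagged untestable.
#'
#' @param profile A [bin_retrieval()] result.
#' @param features Data frame with `kind`, `start`, `end` (0-based
#'   half-open, cMAG coordinates).
#' @return Data frame with one row per kind: `kind`, `n_bins_with`,
#'   `n_bins_without`, `U`, `p`, `testable`.
#' @export
feature_rate_test <- function(profile, features) {
  bins <- profile$bins
  out <- lapply(unique(features$kind), function(k) {
    f <- features[features$kind == k, , drop = FALSE]
    with_feat <- vapply(seq_len(nrow(bins)), function(i) {
      any(f$start < bins$bin_end[i] & f$end > bins$bin_start[i])
    }, logical(1))
    a <- bins$rate[with_feat]
    b <- bins$rate[!with_feat]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(kind = k, n_bins_with = length(a),
                        n_bins_without = length(b), U = NA_real_,
                        p = NA_real_, testable = FALSE))
    }
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided",
                  exact = FALSE, correct = TRUE))
    data.frame(kind = k, n_bins_with = length(a),
               n_bins_without = length(b),
               U = unname(wt$statistic), p = wt$p.value, testable = TRUE)
  })
  do.call(rbind, out)
}
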