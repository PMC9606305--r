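test_that("GC skew of a G-half/C-half sequence peaks at the boundary", {
  s <- paste0(strrep("G", 2500), strrep("C", 2500))
  p <- gc_skew(c(x = s), window = 1000, step = 10, circular = FALSE)
  expect_identical(length(p$skew), 401L)  # floor((L - w)/step) + 1
  expect_equal(p$skew[1], 1)              # all-G window
  expect_equal(p$skew[length(p$skew)], -1)
  # cumulative maximum (terminus analogue) where the window crosses the
  # boundary at its midpoint: start ~2000
  expect_gte(p$ter_pos, 1900)
  expect_lte(p$ter_pos, 2100)
  expect_true(all(abs(p$skew) <= 1))
})

test_that("reverse complement negates the skew series", {
  set.seed(61)
  s <- random_dna(5000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  p1 <- gc_skew(c(x = s), circular = FALSE)
  p2 <- gc_skew(c(x = rc), circular = FALSE)
  expect_equal(p2$skew, -rev(p1$skew))
})

test_that("an AT-only sequence has zero skew everywhere", {
  s <- strrep("AT", 1500)
  p <- gc_skew(c(x = s), circular = FALSE)
  expect_true(all(p$skew == 0))
})

test_that("circular traversal makes rotation a cyclic shift", {
  set.seed(62)
  s <- random_dna(4000)
  rot <- paste0(substring(s, 501), substr(s, 1, 500))  # rotate by 500
  p1 <- gc_skew(c(x = s), circular = TRUE)
  p2 <- gc_skew(c(x = rot), circular = TRUE)
  expect_identical(length(p1$skew), 400L)   # every position covered
  shift <- 500 / 10
  expect_equal(p2$skew, c(p1$skew[(shift + 1):400], p1$skew[1:shift]))
})

test_that("contigs shorter than the window are refused", {
  expect_error(gc_skew(c(x = strrep("A", 500))), "shorter than")
})

test_that("SNV counts are exact for planted substitutions, indels excluded", {
  set.seed(63)
  ref <- random_dna(8000)
  sub_pos <- spaced_positions(7, 200, 7800, 1000)
  q_subs <- plant_substitutions(ref, sub_pos)
  sv <- call_snvs(c(q = q_subs), c(r = ref))
  expect_identical(sv$snv_count, 7L)

  q_mixed <- plant_insertions(plant_substitutions(ref, sub_pos[1:3]),
                              c(2500, 5500), 8)
  sv2 <- call_snvs(c(q = q_mixed), c(r = ref))
  expect_identical(sv2$snv_count, 3L)       # insertions not counted

  sv3 <- call_snvs(c(q = ref), c(r = ref))
  expect_identical(sv3$snv_count, 0L)
  expect_identical(sv3$aligned_bases, 8000L)

  expect_warning(sv4 <- call_snvs(c(q = random_dna(3000)),
                                  c(r = random_dna(3000))),
                 "no alignment")
  expect_true(sv4$no_alignment)
})

test_that("SNV percentile is rank among conspecific densities", {
  dens <- (0:100) / 1000
  expect_equal(snv_percentile(dens[51], dens), 51 / 101)
  expect_identical(snv_percentile(-1, dens), 0)
  expect_identical(snv_percentile(1, dens), 1)
  expect_error(snv_percentile(0.05, dens[1:99]), "refusing to rank")
  expect_silent(snv_percentile(0.05, dens[1:10], min_n = 10))
})

test_that("bin retrieval implements the printed formula", {
  set.seed(64)
  cm <- random_dna(10000)
  full <- lapply(1:10, function(i) c(chr = cm))
  names(full) <- sprintf("g%02d", 1:10)
  pr <- bin_retrieval(c(q = cm), full)
  expect_true(all(pr$bins$rate == 100))     # all genomes match every bin

  half <- c(full[1:5], lapply(6:10, function(i) c(chr = random_dna(10000))))
  names(half) <- sprintf("g%02d", 1:10)
  pr2 <- bin_retrieval(c(q = cm), half)
  expect_true(all(abs(pr2$bins$rate - 50) < 1))  # 5 of 10 genomes match

  single <- bin_retrieval(c(q = cm), list(g1 = c(chr = cm)))
  expect_true(all(single$bins$rate == 100))
})

test_that("rates are order-invariant, bounded, and conserve match counts", {
  set.seed(65)
  cm <- random_dna(12000)
  genomes <- list(
    g1 = c(chr = cm),
    g2 = c(chr = substr(cm, 1, 6000)),
    g3 = c(chr = random_dna(12000))
  )
  pr <- bin_retrieval(c(q = cm), genomes)
  pr_rev <- bin_retrieval(c(q = cm), rev(genomes))
  expect_equal(pr$bins$rate, pr_rev$bins$rate)
  expect_true(all(pr$bins$rate >= 0 & pr$bins$rate <= 100))
  width <- pr$bins$bin_end - pr$bins$bin_start
  expect_equal(sum(pr$bins$rate * width * pr$n_conspecific / 100),
               pr$total_matched, tolerance = 1e-8)
})

test_that("a region absent from all genomes yields one low segment", {
  set.seed(66)
  left <- random_dna(7000); mid <- random_dna(7000); right <- random_dna(6000)
  cm <- paste0(left, mid, right)
  genomes <- lapply(1:5, function(i) c(chr = paste0(left, right)))
  names(genomes) <- sprintf("g%02d", 1:5)
  pr <- bin_retrieval(c(q = cm), genomes)
  expect_identical(nrow(pr$low_segments), 1L)
  expect_identical(pr$low_segments$end_bin - pr$low_segments$start_bin + 1L,
                   7L)                       # 7 consecutive 1-kbp bins
  expect_identical(pr$low_segments$start_bin, 8L)
})

test_that("trailing partial bins normalize by width by default", {
  set.seed(67)
  cm <- random_dna(10500)
  pr_w <- bin_retrieval(c(q = cm), list(g = c(chr = cm)))
  pr_f <- bin_retrieval(c(q = cm), list(g = c(chr = cm)),
                        partial = "fixed")
  last <- nrow(pr_w$bins)
  expect_equal(pr_w$bins$rate[last], 100)
  expect_equal(pr_f$bins$rate[last], 50)
})

test_that("feature bins separate cleanly under the rank test", {
  prof <- list(bins = data.frame(bin_start = (0:99) * 1000,
                                 bin_end = (1:100) * 1000,
                                 rate = rep(c(0, 100), each = 50)))
  feats <- data.frame(kind = "genomic_island", start = 0, end = 50000)
  res <- feature_rate_test(prof, feats)
  expect_true(res$testable)
  expect_identical(res$n_bins_with, 50L)
  expect_lt(res$p, 1e-6)

  one_bin <- data.frame(kind = "rRNA5S", start = 0, end = 500)
  res2 <- feature_rate_test(prof, one_bin)
  expect_false(res2$testable)
})
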