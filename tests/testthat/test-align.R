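test_that("identical sequences align as one full-identity block", {
  set.seed(21)
  a <- random_dna(20000)
  blocks <- align(c(r = a), c(q = a))
  expect_identical(nrow(blocks), 1L)
  expect_equal(blocks$identity, 1.0)
  s <- summarize_alignment(blocks, 20000, 20000)
  expect_equal(s$ani, 1.0)
  expect_equal(s$max_alignment_coverage, 1.0)
})

test_that("self-alignment of random sequences is exactly ANI 1, coverage 1", {
  set.seed(22)
  for (len in c(2000, 11000, 50000)) {
    a <- random_dna(len)
    s <- pairwise_compare(c(x = a), c(y = a))
    expect_identical(s$ani, 1.0)
    expect_identical(s$max_alignment_coverage, 1.0)
  }
})

test_that("regular substitutions give ~0.99 identity, agreeing with full DP", {
  set.seed(23)
  a <- random_dna(5000)
  m <- plant_substitutions(a, seq(50, 4950, by = 100))   # one per 100 bp
  blocks <- best_bidirectional(align(c(r = a), c(q = m)))
  s <- summarize_alignment(blocks, 5000, 5000)
  expect_lt(abs(s$ani - 0.99), 0.002)
  expect_lt(abs(sum(blocks$matches) - oracle_global_matches(a, m)) /
              oracle_global_matches(a, m), 0.02)
})

test_that("independent random sequences yield no credible block", {
  set.seed(24)
  for (i in 1:20) {
    blocks <- align(c(r = random_dna(10000)), c(q = random_dna(10000)))
    bad <- blocks$identity >= 0.95 &
      (blocks$ref_end - blocks$ref_start) >= 1000
    expect_false(any(bad))
  }
})

test_that("strand symmetry: reverse-complement query flips strands only", {
  set.seed(25)
  a <- random_dna(20000)
  m <- plant_substitutions(a, spaced_positions(100, 10, 19900, 150))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  s_f <- pairwise_compare(c(r = a), c(q = m))
  s_r <- pairwise_compare(c(r = a), c(q = rc))
  expect_lt(abs(s_f$ani - s_r$ani), 1e-9)
  expect_lt(abs(s_f$max_alignment_coverage - s_r$max_alignment_coverage),
            1e-9)
  expect_identical(unique(align(c(r = a), c(q = rc))$strand), "-")
})

test_that("ANI is nearly symmetric in alignment direction", {
  set.seed(26)
  sp <- make_species(50000, 2, 0.01, 1e-4, seed = 26)
  g <- sp$genomes
  ab <- pairwise_compare(c(a = g[[1]]), c(b = g[[2]]))
  ba <- pairwise_compare(c(b = g[[2]]), c(a = g[[1]]))
  expect_lt(abs(ab$ani - ba$ani), 0.005)
})

test_that("maxmatch mode recovers repeated copies that unique anchors skip", {
  set.seed(27)
  core <- random_dna(3000)
  ref <- paste0(random_dna(2000), core, random_dna(1500), core,
                random_dna(1000))
  bl_max <- align(c(r = ref), c(q = core), mode = "maxmatch")
  spans <- IRanges::reduce(IRanges::IRanges(bl_max$ref_start + 1,
                                            bl_max$ref_end))
  expect_gte(length(spans), 2L)   # both copies found
  expect_gte(sum(IRanges::width(spans)), 2 * 3000 * 0.95)
})

test_that("non-ACGTN symbols are rejected", {
  expect_error(align(c(r = "ACGTQ"), c(q = "ACGT")), "outside")
})

test_that("best-bidirectional filtering is greedy by score with 50 bp slack", {
  mk <- function(rs, re, qs, qe, m) {
    data.frame(ref_contig = "r", qry_contig = "q", ref_start = rs,
               ref_end = re, qry_start = qs, qry_end = qe, strand = "+",
               matches = m, mismatches = 0, aligned_length = re - rs,
               identity = m / (re - rs))
  }
  disjoint <- rbind(mk(0, 1000, 0, 1000, 900), mk(2000, 3000, 2000, 3000,
                                                  800))
  expect_identical(nrow(best_bidirectional(disjoint)), 2L)

  dominated <- rbind(mk(0, 1000, 0, 1000, 900), mk(0, 1000, 5000, 6000,
                                                   500))
  kept <- best_bidirectional(dominated)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$matches, 900)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    rs <- sample(0:500, n); qs <- sample(0:500, n)
    blocks <- do.call(rbind, lapply(seq_len(n), function(j) {
      mk(rs[j], rs[j] + 400, qs[j], qs[j] + 400, sample(200:400, 1))
    }))
    kept <- best_bidirectional(blocks)
    if (nrow(kept) >= 2) {
      for (x in seq_len(nrow(kept) - 1)) {
        for (y in seq(x + 1, nrow(kept))) {
          ov_r <- min(kept$ref_end[c(x, y)]) - max(kept$ref_start[c(x, y)])
          ov_q <- min(kept$qry_end[c(x, y)]) - max(kept$qry_start[c(x, y)])
          expect_lte(ov_r, 50)
          expect_lte(ov_q, 50)
        }
      }
    }
  }
})

test_that("summaries implement the printed ratios", {
  blocks <- data.frame(ref_contig = "r", qry_contig = "q",
                       ref_start = 0L, ref_end = 1900L,
                       qry_start = 0L, qry_end = 1900L, strand = "+",
                       matches = 1881, mismatches = 19,
                       aligned_length = 1900, identity = 1881 / 1900)
  s <- summarize_alignment(blocks, 2000, 2000)
  expect_equal(s$ani, 0.99)
  expect_equal(s$max_alignment_coverage, 0.95)
  expect_equal(s$similarity_index, 0.9405)

  empty <- summarize_alignment(blocks[0, ], 1000, 1000)
  expect_identical(empty$ani, 0)
  expect_identical(empty$max_alignment_coverage, 0)
  expect_identical(empty$similarity_index, 0)
})

test_that("pairwise summary enforces the similarity-index invariant", {
  s <- pairwise_summary(0.99, 0.95)
  expect_equal(s$similarity_index, 0.9405)
  expect_error(pairwise_summary(1.2, 0.5))
})
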