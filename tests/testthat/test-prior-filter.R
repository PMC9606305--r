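full_annotation <- function(id = "c1", n_markers = 120, n_trna = 22,
                            rrna_types = c("5S", "16S", "23S"),
                            marker_ns = "bac120") {
  annotation_set(
    id,
    marker_ids = sprintf("%s_m%03d", marker_ns, seq_len(n_markers)),
    rrna = if (length(rrna_types)) {
      data.frame(contig_id = id, type = rrna_types,
                 start = 100L * seq_along(rrna_types),
                 end = 100L * seq_along(rrna_types) + 50L, strand = "+")
    } else empty_rrna(),
    trna = if (n_trna > 0) {
      data.frame(contig_id = id, isotype = sprintf("iso%02d",
                                                   seq_len(n_trna)),
                 pseudo = FALSE, start = 10L * seq_len(n_trna),
                 end = 10L * seq_len(n_trna) + 5L)
    } else NULL
  )
}

test_that("tRNA isotype counting is distinct and non-pseudo only", {
  a <- full_annotation(n_trna = 20)
  expect_identical(count_trna_types(a), 20L)

  rep_one <- annotation_set("c1", trna = data.frame(
    contig_id = "c1", isotype = rep("Ala", 25), pseudo = FALSE,
    start = 1:25, end = 26:50))
  expect_identical(count_trna_types(rep_one), 1L)

  mixed <- annotation_set("c1", trna = data.frame(
    contig_id = "c1",
    isotype = c(sprintf("iso%02d", 1:19), sprintf("pseudo%02d", 1:5)),
    pseudo = c(rep(FALSE, 19), rep(TRUE, 5)),
    start = 1:24, end = 31:54))
  expect_identical(count_trna_types(mixed), 19L)
})

test_that("a clean 2 Mbp contig passes; single deficits fail with reasons", {
  ok <- apply_prior_filter("c1", 2e6, TRUE, full_annotation())
  expect_true(ok$passed)

  few_markers <- apply_prior_filter("c1", 2e6, TRUE,
                                    full_annotation(n_markers = 99))
  expect_false(few_markers$passed)
  fail <- few_markers$reasons[!few_markers$reasons$passed, ]
  expect_identical(fail$criterion, "marker_count")
  expect_identical(fail$observed, "99")

  no16s <- apply_prior_filter("c1", 2e6, TRUE,
                              full_annotation(rrna_types = c("5S", "23S")))
  expect_false(no16s$passed)
  fail <- no16s$reasons[!no16s$reasons$passed, ]
  expect_identical(fail$criterion, "rRNA")
  expect_match(fail$observed, "16S")
})

test_that("thresholds are inclusive at the printed boundaries", {
  expect_true(apply_prior_filter("c1", 100000, TRUE,
                                 full_annotation(n_markers = 100,
                                                 n_trna = 20))$passed)
  expect_false(apply_prior_filter("c1", 99999, TRUE,
                                  full_annotation())$passed)
  expect_false(apply_prior_filter("c1", 2e6, TRUE,
                                  full_annotation(n_trna = 19))$passed)
})

test_that("every criterion is evaluated, no short-circuit", {
  bad <- apply_prior_filter("c1", 50000, FALSE,
                            full_annotation(n_markers = 10, n_trna = 3,
                                            rrna_types = character(0)),
                            in_bubble = TRUE, is_repeat = TRUE)
  expect_false(bad$passed)
  expect_identical(nrow(bad$reasons), 7L)
  expect_identical(sum(!bad$reasons$passed), 7L)
})

test_that("graph flags and non-circularity each reject", {
  expect_false(apply_prior_filter("c1", 2e6, TRUE, full_annotation(),
                                  in_bubble = TRUE)$passed)
  expect_false(apply_prior_filter("c1", 2e6, TRUE, full_annotation(),
                                  is_repeat = TRUE)$passed)
  expect_false(apply_prior_filter("c1", 2e6, FALSE,
                                  full_annotation())$passed)
})

test_that("the marker threshold applies to the dominant namespace", {
  arc <- full_annotation(n_markers = 105, marker_ns = "arc122")
  arc$marker_ids <- c(arc$marker_ids, sprintf("bac120_m%03d", 1:8))
  expect_true(apply_prior_filter("c1", 2e6, TRUE, arc)$passed)
})

test_that("rRNA requirement can be relaxed to any-of", {
  ann <- full_annotation(rrna_types = "16S")
  strict <- apply_prior_filter("c1", 2e6, TRUE, ann)
  relaxed <- apply_prior_filter("c1", 2e6, TRUE, ann,
                                thresholds = prior_thresholds(
                                  rrna_mode = "any"))
  expect_false(strict$passed)
  expect_true(relaxed$passed)
})

test_that("adding markers, tRNAs or rRNAs never flips PASS to FAIL", {
  set.seed(12)
  for (i in 1:25) {
    n_mk <- sample(80:130, 1)
    n_tr <- sample(15:25, 1)
    rr <- sample(c("5S", "16S", "23S"), sample(0:3, 1))
    base <- apply_prior_filter("c1", 2e6, TRUE,
                               full_annotation(n_markers = n_mk,
                                               n_trna = n_tr,
                                               rrna_types = rr))
    more <- apply_prior_filter("c1", 2e6, TRUE,
                               full_annotation(n_markers = n_mk + 10,
                                               n_trna = n_tr + 3,
                                               rrna_types = c("5S", "16S",
                                                              "23S")))
    if (base$passed) expect_true(more$passed)
  }
})
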