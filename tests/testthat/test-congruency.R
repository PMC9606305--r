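# catalogs built from shared random blocks so presence/absence is known
# exactly by construction

shared_block_catalog <- function(layout, blocks, genus = "TestGenus",
                                 isolate = logical(length(layout))) {
  genomes <- lapply(layout, function(cn) setNames(blocks[cn], cn))
  meta <- data.frame(genome_id = names(layout),
                     species_cluster_id = "SC1", genus = genus,
                     is_representative = seq_along(layout) == 1L,
                     is_isolate = isolate,
                     is_complete = isolate)
  genome_catalog(genomes, meta)
}

test_that("conspecificity and isolate rules use strict printed bounds", {
  expect_true(is_conspecific(0.96, 0.85))
  expect_true(is_conspecific(0.9501, 0.8001))
  expect_false(is_conspecific(0.95, 0.9))      # ANI boundary strict
  expect_false(is_conspecific(0.96, 0.8))      # coverage boundary strict
  expect_true(is_conspecific(0.945, 0.9, ani_threshold = 0.94))
  expect_false(is_conspecific(0.97, 0.6, cov_threshold = 0.6))
  expect_true(is_conspecific(0.97, 0.7, cov_threshold = 0.6))
})

test_that("a planted species is recovered as conspecific members", {
  sp <- make_species(40000, 10, 0.01, seed = 51)
  genomes <- lapply(names(sp$genomes), function(g) {
    setNames(sp$genomes[g], "chr")
  })
  names(genomes) <- names(sp$genomes)
  meta <- data.frame(genome_id = names(genomes),
                     species_cluster_id = "SC1", genus = "TestGenus",
                     is_representative = seq_along(genomes) == 1L,
                     is_isolate = FALSE, is_complete = FALSE)
  cat10 <- genome_catalog(genomes, meta)
  q <- c(query = mutate_sequence(sp$ancestor, 0.01)$sequence)
  cs <- find_conspecific(q, cat10, "TestGenus")
  expect_identical(nrow(cs$members), 10L)
  expect_true(all(cs$members$ani > 0.95))
  expect_true(all(cs$members$max_alignment_coverage > 0.8))
  expect_false(cs$capped)

  none <- find_conspecific(q, cat10, "OtherGenus")
  expect_identical(nrow(none$members), 0L)
})

test_that("per-genus ANI overrides are applied", {
  sp <- make_species(20000, 2, 0.01, seed = 52)
  genomes <- list(g1 = c(chr = sp$genomes[[1]]),
                  g2 = c(chr = sp$genomes[[2]]))
  meta <- data.frame(genome_id = c("g1", "g2"),
                     species_cluster_id = "SC1", genus = "Collinsella",
                     is_representative = c(TRUE, FALSE),
                     is_isolate = FALSE, is_complete = FALSE)
  ctl <- genome_catalog(genomes, meta)
  q <- c(query = mutate_sequence(sp$ancestor, 0.01)$sequence)
  cs <- find_conspecific(q, ctl, "Collinsella")
  expect_equal(cs$ani_threshold, 0.94)
})

test_that("core contigs follow the length and presence rules exactly", {
  set.seed(53)
  A <- random_dna(8000)    # shared by all
  B <- random_dna(4000)    # shared by all but too short
  Y <- random_dna(6000)    # in 8 of 10 genomes
  X <- random_dna(7000)    # mobile: in 1 genome only
  blocks <- c(A = A, B = B, Y = Y, X = X)
  layout <- c(
    list(G01 = c("A", "B", "Y", "X")),
    lapply(2:8, function(i) c("A", "B", "Y")),
    lapply(9:10, function(i) c("A", "B"))
  )
  names(layout) <- sprintf("G%02d", 1:10)
  genomes <- lapply(layout, function(cn) setNames(blocks[cn], cn))
  core <- identify_core_contigs(genomes)
  tab <- core$table

  a_rows <- tab[tab$contig_id == "A", ]
  expect_true(all(a_rows$presence_fraction == 1))
  expect_true(all(a_rows$core))

  b_rows <- tab[tab$contig_id == "B", ]
  expect_true(all(b_rows$presence_fraction == 1))
  expect_false(any(b_rows$core))          # 4 kbp: length rule (> 5 kbp)

  y1 <- tab[tab$contig_id == "Y" & tab$genome_id == "G01", ]
  expect_equal(y1$presence_fraction, 7 / 9)   # 0.78 < 0.8: not core
  expect_false(y1$core)

  x1 <- tab[tab$contig_id == "X", ]
  expect_equal(x1$presence_fraction, 0)       # mobile element never core
  expect_false(x1$core)
})

test_that("boundary semantics of the core rule", {
  expect_false(is_core(5000, 0.9))    # length strictly > 5 kbp
  expect_true(is_core(5001, 0.9))
  expect_false(is_core(6000, 0.8))    # presence strictly > 0.8
  expect_true(is_core(6000, 0.8001))
})

test_that("retrieval rate and verdicts react to planted deletions", {
  set.seed(54)
  A <- random_dna(8000)
  B <- random_dna(7000)
  blocks <- c(A = A, B = B)
  layout <- lapply(1:6, function(i) c("A", "B"))
  names(layout) <- sprintf("G%02d", 1:6)
  genomes <- lapply(layout, function(cn) setNames(blocks[cn], cn))
  core <- identify_core_contigs(genomes)
  expect_identical(length(core$sequences), 12L)   # A and B per genome

  full_query <- c(q = paste0(A, random_dna(2000), B))
  dec_full <- core_retrieval_rate(full_query, core, 6)
  expect_equal(dec_full$retrieval_rate, 1.0)
  expect_identical(dec_full$verdict, "accept")

  gapped_query <- c(q = paste0(A, random_dna(2000)))   # B deleted
  dec_gap <- core_retrieval_rate(gapped_query, core, 6)
  expect_equal(dec_gap$retrieval_rate, 0.5)
  expect_identical(dec_gap$verdict, "reject_low_retrieval")
  # monotone: deleting core contigs cannot raise the rate
  expect_lte(dec_gap$retrieval_rate, dec_full$retrieval_rate)

  dec_few <- core_retrieval_rate(full_query, core, 4)
  expect_identical(dec_few$verdict, "reject_few_conspecific")
})

test_that("verdict boundaries: rate 0.95 and 5 genomes are inclusive", {
  expect_identical(congruency_verdict(0.95, 5), "accept")
  expect_identical(congruency_verdict(0.9499, 5), "reject_low_retrieval")
  expect_identical(congruency_verdict(1.0, 4), "reject_few_conspecific")
  expect_identical(congruency_verdict(NA_real_, 10),
                   "reject_low_retrieval")
})

test_that("culturability needs an isolate at ANI > 0.95 and coverage > 0.6", {
  set.seed(55)
  base <- random_dna(30000)
  q <- c(q = plant_substitutions(base, spaced_positions(30, 10, 29000, 900)))

  iso_cat <- shared_block_catalog(
    list(g1 = "chr"), c(chr = base), isolate = TRUE)
  res <- culturability(q, iso_cat)
  expect_true(res$has_isolate_conspecific)
  expect_true(res$has_complete_isolate)

  mag_cat <- shared_block_catalog(
    list(g1 = "chr"), c(chr = base), isolate = FALSE)
  res2 <- culturability(q, mag_cat)
  expect_false(res2$has_isolate_conspecific)
  expect_false(res2$has_complete_isolate)

  # same length but only ~55% homologous: coverage below the 0.6 bound
  half <- c(chr = paste0(substr(base, 1, 16500), random_dna(13500)))
  half_cat <- shared_block_catalog(list(g1 = "chr"), half, isolate = TRUE)
  res3 <- culturability(q, half_cat)
  expect_false(res3$has_isolate_conspecific)
})
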