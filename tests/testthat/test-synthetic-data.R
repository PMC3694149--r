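test_that("transcriptome simulation is deterministic and validates input", {
  a <- simulate_transcriptome(20, c(50, 80), seed = 101)
  b <- simulate_transcriptome(20, c(50, 80), seed = 101)
  c <- simulate_transcriptome(20, c(50, 80), seed = 102)
  expect_identical(a, b)
  expect_false(identical(a$sequence, c$sequence))
  expect_true(all(nchar(a$sequence) >= 50 & nchar(a$sequence) <= 80))
  expect_equal(nrow(simulate_transcriptome(0)), 0L)
  expect_error(simulate_transcriptome(-1), "non-negative")

  fa <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts_fasta(a, fa)
  write_transcripts_fasta(b, fa2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_equal(read_transcripts(fa), a)
})

test_that("CATG occurrence frequency matches the exact automaton DP", {
  L <- 300
  n <- 5000
  tr <- simulate_transcriptome(n, c(L, L), seed = 103)
  observed <- mean(grepl("CATG", tr$sequence, fixed = TRUE))
  expected <- catg_contain_prob(L)
  tol <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), tol)
  # the DP itself against tiny-case enumeration: L = 4 has exactly one
  # window, so P = 1/256
  expect_equal(catg_contain_prob(4), 1 / 256, tolerance = 1e-12)
  expect_equal(catg_contain_prob(3), 0)
})

test_that("expression truth lives on the simplex with planted folds", {
  ids <- sprintf("g%03d", 1:500)
  tr0 <- simulate_expression(ids, de_fraction = 0, seed = 104)
  expect_equal(unname(colSums(tr0$stage_props)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(tr0$stage_props[, 1]), tr0$genes$baseline_prop,
               tolerance = 1e-12)
  expect_false(any(tr0$genes$de_flag))

  tr1 <- simulate_expression(ids, de_fraction = 0.2, fold_levels = 4,
                             seed = 105)
  expect_equal(unname(colSums(tr1$stage_props)), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(tr1$genes$de_flag), 100)
  expect_equal(tr1$genes$de_flag,
               unname(apply(tr1$multipliers != 1, 1, any)))
  # a planted 4-fold gene's stage ratio is 4 x the renormalisation factor
  g <- which(tr1$genes$de_flag & tr1$genes$fold == 4 &
               tr1$genes$onset_stage == 2)[1]
  renorm <- sum(tr1$multipliers[, 2] * tr1$genes$baseline_prop)
  expect_equal(tr1$stage_props[g, 2] / tr1$stage_props[g, 1],
               4 / renorm, tolerance = 1e-9)
  expect_error(simulate_expression(ids, de_fraction = 0.5,
                                   fold_levels = numeric(0)), "fold_levels")
})

test_that("library simulation keeps totals exact and is seed-stable", {
  tr <- simulate_transcriptome(200, seed = 106)
  idx <- build_virtual_tag_index(tr)
  truth <- simulate_expression(tr$gene_id, seed = 107)
  lib <- simulate_tag_library(truth, idx, 1, depth = 30000, seed = 108)
  expect_equal(lib$total_raw, 30000)
  lib2 <- simulate_tag_library(truth, idx, 1, depth = 30000, seed = 108)
  expect_identical(lib$counts, lib2$counts)
  expect_equal(simulate_tag_library(truth, idx, 1, depth = 0,
                                    seed = 1)$total_raw, 0)
  expect_error(simulate_tag_library(truth, idx, 1, depth = -5), ">= 0")
})

test_that("noiseless libraries map with zero unknown tags", {
  set.seed(109)
  study <- simulate_study(n_genes = 250, depth = 20000, error_rate = 0,
                          n_rate = 0, artifact_rate = 0, seed = 109)
  clean <- clean_tags(study$libraries$L1)
  a <- map_tags(clean, study$index)
  expect_false(any(a$status == "unknown"))
})

test_that("sampled gene counts follow the planted proportions", {
  tr <- simulate_transcriptome(300, seed = 110)
  idx <- build_virtual_tag_index(tr)
  truth <- simulate_expression(tr$gene_id, de_fraction = 0, seed = 111)
  depth <- 1e6
  lib <- simulate_tag_library(truth, idx, 1, depth = depth, error_rate = 0,
                              n_rate = 0, artifact_rate = 0, seed = 112)
  sense1 <- idx$tags[idx$tags$strand == "sense" & idx$tags$site_rank == 1, ]
  props <- truth$stage_props[match(sense1$gene_id, truth$genes$gene_id), 1]
  props <- props / sum(props)
  # check the most abundant observable gene against its binomial law
  top <- which.max(props)
  p <- props[top]
  observed <- sum(lib$counts[names(lib$counts) == sense1$tag_seq[top]])
  expect_lt(abs(observed - depth * p), 3 * sqrt(depth * p * (1 - p)) + 1)
})

test_that("error and N injection land in the variable region at the set rate", {
  tr <- simulate_transcriptome(100, seed = 113)
  idx <- build_virtual_tag_index(tr)
  truth <- simulate_expression(tr$gene_id, de_fraction = 0, seed = 114)
  lib <- simulate_tag_library(truth, idx, 1, depth = 2e5, error_rate = 0.01,
                              n_rate = 0.005, artifact_rate = 0, seed = 115)
  expect_equal(lib$total_raw, 2e5)
  seqs <- names(lib$counts)
  expect_true(all(startsWith(seqs, "CATG")))   # anchor never mutated
  n_copies <- sum(lib$counts[grepl("N", seqs, fixed = TRUE)])
  # N replacement applies to copies left intact by the error step
  p_err <- 1 - (1 - 0.01)^17
  expected <- 0.005 * (1 - p_err)
  expect_lt(abs(n_copies / 2e5 - expected),
            3 * sqrt(expected / 2e5) + 1e-4)
})
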