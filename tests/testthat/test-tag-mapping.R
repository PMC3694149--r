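toy_index <- function() build_virtual_tag_index(toy_reference())

test_that("exact, one-mismatch, ambiguous and unknown verdicts are correct", {
  idx <- toy_index()
  tagA <- paste0("CATG", strrep("A", 17))        # gA and gC exactly
  tagB <- paste0("CATG", "GTACGTACGTACGTACG")    # gB exactly
  tagB1 <- paste0("CATG", "GTACGTACGTACGTACC")   # 1 mismatch from gB only
  far <- paste0("CATG", strrep("C", 17))         # >= 2 from everything
  cl <- toy_clean(setNames(c(4, 6, 3, 2), c(tagA, tagB, tagB1, far)))
  a <- map_tags(cl, idx)
  row <- function(t) a[a$tag_seq == t, ]
  expect_equal(row(tagB)$status, "unambiguous")
  expect_equal(row(tagB)$gene_id, "gB")
  expect_equal(row(tagB)$mismatches, 0L)
  expect_equal(row(tagB1)$status, "unambiguous")
  expect_equal(row(tagB1)$gene_id, "gB")
  expect_equal(row(tagB1)$mismatches, 1L)
  expect_equal(row(tagA)$status, "ambiguous")   # shared by gA and gC
  expect_equal(row(far)$status, "unknown")
  expect_true(is.na(row(far)$mismatches))
})

test_that("several sites of the same gene never create ambiguity", {
  tr <- data.frame(gene_id = "multi",
                   sequence = paste0("CATGCATG", strrep("A", 17)))
  idx <- build_virtual_tag_index(tr)
  tag <- paste0("CATG", strrep("A", 17))
  a <- map_tags(toy_clean(setNames(5, tag)), idx)
  expect_equal(a$status, "unambiguous")
  expect_equal(a$gene_id, "multi")
})

test_that("an exact hit suppresses one-mismatch hits to other genes", {
  tr <- data.frame(
    gene_id = c("exact", "near"),
    sequence = c(paste0("CATG", strrep("A", 17)),
                 paste0("CATG", strrep("A", 16), "C")))
  idx <- build_virtual_tag_index(tr)
  tag <- paste0("CATG", strrep("A", 17))
  a <- map_tags(toy_clean(setNames(3, tag)), idx)
  expect_equal(a$status, "unambiguous")
  expect_equal(a$gene_id, "exact")
  expect_equal(a$mismatches, 0L)
})

test_that("mapping equals the brute-force Hamming oracle on random instances", {
  set.seed(61)
  for (rep in 1:20) {
    nv <- sample(20:80, 1)
    vtags <- paste0("CATG", vapply(seq_len(nv), function(i) random_seq(17),
                                   character(1)))
    vgenes <- sprintf("g%02d", sample(1:25, nv, replace = TRUE))
    idx <- list(tags = data.frame(tag_seq = vtags, gene_id = vgenes,
                                  strand = "sense", site_rank = 1L,
                                  stringsAsFactors = FALSE),
                n_genes = 25L, n_catg_genes = length(unique(vgenes)),
                gene_ids = sprintf("g%02d", 1:25))
    idx$lookup <- tagdge:::build_index_lookup(idx$tags)
    class(idx) <- "virtual_tag_index"
    nq <- sample(10:50, 1)
    # mix of exact copies, perturbed copies and random tags
    qt <- unique(c(sample(vtags, min(nq, nv)),
                   paste0("CATG", vapply(seq_len(nq), function(i)
                     random_seq(17), character(1)))))
    cl <- toy_clean(setNames(sample(2:9, length(qt), replace = TRUE), qt))
    got <- map_tags(cl, idx)
    want <- hamming_map_oracle(names(cl$counts), vtags, vgenes)
    o <- order(got$tag_seq)
    w <- order(want$tag_seq)
    expect_equal(got$status[o], want$status[w])
    expect_equal(got$gene_id[o], want$gene_id[w])
    expect_equal(got$mismatches[o], want$mismatches[w])
  }
})

test_that("verdicts partition the tags and are order-independent", {
  set.seed(62)
  idx <- build_virtual_tag_index(random_transcripts(30))
  tags <- unique(c(sample(idx$tags$tag_seq, 10),
                   paste0("CATG", vapply(1:30, function(i) random_seq(17),
                                         character(1)))))
  counts <- setNames(sample(2:20, length(tags), replace = TRUE), tags)
  cl1 <- toy_clean(counts)
  cl2 <- toy_clean(rev(counts))
  a1 <- map_tags(cl1, idx)
  a2 <- map_tags(cl2, idx)
  expect_setequal(a1$tag_seq, a2$tag_seq)
  m <- match(a1$tag_seq, a2$tag_seq)
  expect_equal(a1$status, a2$status[m])
  expect_equal(a1$gene_id, a2$gene_id[m])
  # partition of copies across the three classes
  expect_equal(sum(a1$copies), cl1$total_clean)
  expect_equal(sum(table(a1$status)), nrow(a1))
})

test_that("library summary reproduces the two-tier table arithmetic", {
  idx <- toy_index()
  tagA <- paste0("CATG", strrep("A", 17))      # ambiguous (gA+gC)
  tagB <- paste0("CATG", "GTACGTACGTACGTACG")  # unambiguous gB
  far <- paste0("CATG", strrep("C", 17))       # unknown
  cl <- toy_clean(setNames(c(10, 30, 10), c(tagA, tagB, far)))
  s <- summarize_library(cl, map_tags(cl, idx), idx)
  expect_equal(s$clean_total, 50)
  expect_equal(s$all_mapped_total, 40)
  expect_equal(s$all_mapped_total_pct, 80)
  expect_equal(s$unambiguous_total, 30)
  expect_equal(s$unambiguous_total_pct, 60)
  expect_equal(s$all_mapped_genes, 3L)          # gA, gB, gC
  expect_equal(s$unambiguous_genes, 1L)         # gB
  expect_equal(s$unambiguous_genes_pct, report_percentage(1, 3))
  expect_equal(s$unknown_total, 10)
  expect_equal(s$unknown_total_pct, 20)
  expect_equal(s$unknown_distinct, 1L)
})

test_that("a library that maps nothing reports 0% mapped, 100% unknown", {
  idx <- toy_index()
  cl <- toy_clean(setNames(c(5, 3), paste0("CATG", c(strrep("C", 17),
                                                     strrep("T", 17)))))
  s <- summarize_library(cl, map_tags(cl, idx), idx)
  expect_equal(s$all_mapped_total_pct, 0)
  expect_equal(s$unknown_total_pct, 100)
  expect_equal(s$unambiguous_genes, 0L)
  empty <- toy_clean(setNames(1, paste0("CATG", strrep("A", 17))))
  expect_error(summarize_library(empty, map_tags(empty, idx), idx),
               "zero clean total")
})

test_that("assignments round-trip through TSV", {
  idx <- toy_index()
  cl <- toy_clean(setNames(c(4, 2),
                           c(paste0("CATG", "GTACGTACGTACGTACG"),
                             paste0("CATG", strrep("C", 17)))))
  a <- map_tags(cl, idx)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(a, tsv)
  back <- read_assignments(tsv)
  expect_equal(back$status, a$status)
  expect_equal(back$gene_id, a$gene_id)
  expect_equal(back$copies, a$copies)
})
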