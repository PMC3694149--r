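test_that("read extraction anchors the first CATG after adaptor trimming", {
  tag <- paste0("CATG", strrep("A", 17))
  raw <- extract_raw_tags(c(paste0(tag, "TCGTATGCC"),   # trailing adaptor
                            paste0("GG", tag)),         # leading bases
                          adaptor = "TCGTATGCC")
  expect_equal(as.vector(raw$counts[tag]), 2)
  expect_equal(raw$empty_reads, 0L)
})

test_that("unextractable reads are tallied as empty, never fatal", {
  raw <- extract_raw_tags(c("CATGAAAA",        # < 21 usable bases
                            "TTTTTTTTTTTTTTTTTTTTTTTT",  # no anchor
                            paste0("CATG", strrep("G", 17))))
  expect_equal(raw$total_raw, 1)
  expect_equal(raw$empty_reads, 2L)
  empty <- extract_raw_tags(character(0))
  expect_equal(empty$total_raw, 0)
  expect_equal(empty$distinct_raw, 0L)
})

test_that("17-base tag dialect is anchored on read-in", {
  raw <- raw_tag_set(setNames(3, strrep("G", 17)))
  expect_equal(names(raw$counts), paste0("CATG", strrep("G", 17)))
})

test_that("cleaning applies the filter cascade with a faithful ledger", {
  t1 <- paste0("CATG", strrep("A", 17))
  t3 <- paste0("CATG", "N", strrep("C", 16))
  t4 <- paste0("CATG", strrep("G", 17))
  raw <- raw_tag_set(setNames(c(5, 1, 3, 2),
                              c(t1, paste0("CATG", strrep("T", 17)), t3, t4)))
  clean <- clean_tags(raw)
  expect_equal(sort(names(clean$counts)), sort(c(t1, t4)))
  expect_equal(clean$total_clean, 7)
  expect_equal(clean$distinct_clean, 2L)
  expect_equal(clean$removal_ledger[["contains_N"]], 3)
  expect_equal(clean$removal_ledger[["singleton"]], 1)
  expect_equal(clean$removal_ledger[["bad_length"]], 0)
})

test_that("all-singleton input empties out; clean input is a fixed point", {
  singles <- raw_tag_set(setNames(c(1, 1),
                                  c(paste0("CATG", strrep("A", 17)),
                                    paste0("CATG", strrep("C", 17)))))
  cl <- clean_tags(singles)
  expect_equal(cl$total_clean, 0)
  expect_equal(cl$removal_ledger[["singleton"]], singles$total_raw)

  good <- raw_tag_set(setNames(c(4, 2),
                               c(paste0("CATG", strrep("G", 17)),
                                 paste0("CATG", strrep("T", 17)))))
  cl1 <- clean_tags(good)
  cl2 <- clean_tags(raw_tag_set(cl1$counts, "lib"))
  expect_equal(cl2$counts, cl1$counts)
  expect_true(all(cl2$removal_ledger == 0))
})

test_that("copy conservation holds on randomised tag sets", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    seqs <- vapply(seq_len(n), function(i) {
      len <- sample(c(17L, 21L, sample(10:25, 1)), 1)
      s <- random_seq(len)
      if (runif(1) < 0.2) substr(s, sample(nchar(s), 1),
                                 sample(nchar(s), 1)) <- "N"
      s
    }, character(1))
    counts <- sample(1:10, n, replace = TRUE)
    raw <- raw_tag_set(setNames(counts, seqs))
    clean <- clean_tags(raw)
    expect_equal(raw$total_raw,
                 clean$total_clean + sum(clean$removal_ledger))
    expect_true(all(clean$counts >= 2))
    expect_true(clean$distinct_clean <= raw$distinct_raw)
    expect_true(all(nchar(names(clean$counts)) == 21L))
    expect_false(any(grepl("N", names(clean$counts), fixed = TRUE)))
  }
})

test_that("copy distribution matches hand binning and sums to one", {
  cl <- toy_clean(setNames(c(2, 2, 7, 150),
                           paste0("CATG", c(strrep("A", 17), strrep("C", 17),
                                            strrep("G", 17), strrep("T", 17)))))
  cd <- copy_distribution(cl)
  expect_equal(cd$distinct_fraction, c(0.5, 0.25, 0, 0, 0, 0.25))
  expect_equal(sum(cd$distinct_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(cd$copy_fraction), 1, tolerance = 1e-9)

  all3 <- toy_clean(setNames(c(3, 3), paste0("CATG", c(strrep("A", 17),
                                                       strrep("C", 17)))))
  expect_equal(copy_distribution(all3)$distinct_fraction[1], 1)
})

test_that("malformed copy bins are rejected", {
  cl <- toy_clean(setNames(4, paste0("CATG", strrep("A", 17))))
  overlap <- data.frame(lower = c(2, 5), upper = c(5, Inf))
  gap <- data.frame(lower = c(2, 8), upper = c(5, Inf))
  finite <- data.frame(lower = 2, upper = 100)
  expect_error(copy_distribution(cl, overlap), "partition")
  expect_error(copy_distribution(cl, gap), "partition")
  expect_error(copy_distribution(cl, finite), "partition")
})

test_that("FASTQ emission and tag extraction round-trip the library", {
  set.seed(52)
  tags <- paste0("CATG", vapply(1:5, function(i) random_seq(17), character(1)))
  raw <- raw_tag_set(setNames(sample(2:6, 5, replace = TRUE), tags))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_tag_fastq(raw, fq, adaptor = "TCGTATGCC")
  back <- extract_raw_tags(read_fastq_sequences(fq), adaptor = "TCGTATGCC")
  expect_equal(back$counts[order(names(back$counts))],
               raw$counts[order(names(raw$counts))])
})

test_that("tag-count TSV input accepts both dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tag_seq\tcount",
               paste0(strrep("A", 17), "\t5"),
               paste0("CATG", strrep("C", 17), "\t3")), tsv)
  raw <- read_tag_counts(tsv, "L1")
  expect_equal(sort(names(raw$counts)),
               sort(paste0("CATG", c(strrep("A", 17), strrep("C", 17)))))
  expect_equal(raw$total_raw, 8)
})
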