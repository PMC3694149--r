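# Raw-tag extraction and clean-tag filtering.
#
# Raw tags are CATG-anchored 21-mers observed in sequencing reads; clean
# tags survive the filtering cascade (malformed length, N content,
# single-copy) with every removed copy attributed to exactly one reason in
# a removal ledger, so raw copies are conserved:
#   total_raw == total_clean + sum(removal_ledger).

#' Construct a raw tag set
#'
#' @param counts Named numeric vector: tag sequence -> copy count (>= 1).
#'   Duplicated sequences are aggregated. 17-base sequences are accepted
#'   and prefixed with the fixed `CATG` anchor.
#' @param library_id Library identifier.
#' @param empty_reads Number of reads that yielded no extractable tag
#'   (informational; empty reads contribute no raw copies).
#' @return An object of class `raw_tag_set` with fields `library_id`,
#'   `counts`, `total_raw`, `distinct_raw`, `empty_reads`.
#' @export
raw_tag_set <- function(counts, library_id = "lib", empty_reads = 0L) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("counts must be named by tag sequence", call. = FALSE)
    }
    if (any(counts < 1)) stop("raw copy counts must be >= 1", call. = FALSE)
    seqs <- toupper(names(counts))
    is17 <- nchar(seqs) == TAG_LENGTH - 4L
    seqs[is17] <- paste0(TAG_ANCHOR, seqs[is17])
    counts <- aggregate_tag_counts(seqs, counts)
  } else {
    counts <- setNames(numeric(0), character(0))
  }
  structure(list(
    library_id = library_id,
    counts = counts,
    total_raw = sum(counts),
    distinct_raw = length(counts),
    empty_reads = as.integer(empty_reads)
  ), class = "raw_tag_set")
}

#' @export
print.raw_tag_set <- function(x, ...) {
  cat("Raw tag set", x$library_id, "-", format(x$total_raw, big.mark = ","),
      "copies,", format(x$distinct_raw, big.mark = ","), "distinct tags\n")
  invisible(x)
}

#' Read sequences from a FASTQ file
#'
#' Four-line FASTQ records; quality strings are ignored (quality enters
#' the pipeline only through `N` calls in the sequence).
#'
#' @param path FASTQ path.
#' @return Character vector of read sequences, upper-cased.
#' @export
read_fastq_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(as.character(ss))
}

#' Extract raw tags from reads
#'
#' Each read yields at most one raw tag: after trimming everything from
#' the first adaptor occurrence onwards, the first CATG anchor followed by
#' at least 17 bases defines the tag (anchor + 17). Reads without an
#' extractable tag are tallied as empty, never fatal.
#'
#' @param reads Character vector of read sequences (e.g. from
#'   [read_fastq_sequences()]).
#' @param adaptor Adaptor sequence to trim ("" disables trimming).
#' @param library_id Library identifier.
#' @return A [raw_tag_set()].
#' @export
extract_raw_tags <- function(reads, adaptor = "", library_id = "lib") {
  reads <- toupper(as.character(reads))
  if (!length(reads)) return(raw_tag_set(numeric(0), library_id, 0L))
  if (nzchar(adaptor)) {
    apos <- regexpr(toupper(adaptor), reads, fixed = TRUE)
    trim <- apos > 0L
    reads[trim] <- substr(reads[trim], 1L, apos[trim] - 1L)
  }
  anchor <- regexpr(TAG_ANCHOR, reads, fixed = TRUE)
  ok <- anchor > 0L & anchor + TAG_LENGTH - 1L <= nchar(reads)
  tags <- substring(reads[ok], anchor[ok], anchor[ok] + TAG_LENGTH - 1L)
  raw_tag_set(aggregate_tag_counts(tags, rep(1, length(tags))),
              library_id, empty_reads = sum(!ok))
}

#' Filter raw tags into clean tags
#'
#' Applies the filtering cascade in fixed order so every removed copy is
#' attributed once: malformed length (not 21 after anchoring), then N
#' content, then single-copy tags. Retained tags therefore have canonical
#' length, no N, and copy count >= 2.
#'
#' @param raw A [raw_tag_set()].
#' @return An object of class `clean_tag_set` with fields `library_id`,
#'   `counts` (all >= 2), `total_clean`, `distinct_clean`,
#'   `removal_ledger` (removed copy totals for `adaptor`, `empty`,
#'   `bad_length`, `contains_N`, `singleton`), `total_raw`,
#'   `distinct_raw`, `empty_reads`.
#' @export
clean_tags <- function(raw) {
  stopifnot(inherits(raw, "raw_tag_set"))
  counts <- raw$counts
  ledger <- c(adaptor = 0, empty = 0, bad_length = 0, contains_N = 0,
              singleton = 0)
  bad_len <- nchar(names(counts)) != TAG_LENGTH
  ledger[["bad_length"]] <- sum(counts[bad_len])
  counts <- counts[!bad_len]
  has_n <- grepl("N", names(counts), fixed = TRUE)
  ledger[["contains_N"]] <- sum(counts[has_n])
  counts <- counts[!has_n]
  single <- counts == 1
  ledger[["singleton"]] <- sum(counts[single])
  counts <- counts[!single]
  structure(list(
    library_id = raw$library_id,
    counts = counts,
    total_clean = sum(counts),
    distinct_clean = length(counts),
    removal_ledger = ledger,
    total_raw = raw$total_raw,
    distinct_raw = raw$distinct_raw,
    empty_reads = raw$empty_reads
  ), class = "clean_tag_set")
}

#' @export
print.clean_tag_set <- function(x, ...) {
  cat("Clean tag set", x$library_id, "-",
      format(x$total_clean, big.mark = ","), "copies,",
      format(x$distinct_clean, big.mark = ","), "distinct tags\n")
  cat("Removed copies:",
      paste(names(x$removal_ledger), x$removal_ledger, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Default copy-number bins
#'
#' The conventional partition of the copy axis `[2, Inf)` used for
#' clean-tag abundance classification: 2-5, 6-10, 11-20, 21-50, 51-100,
#' >100 copies.
#'
#' @return Data frame with columns `label`, `lower`, `upper`.
#' @export
default_copy_bins <- function() {
  data.frame(label = c("2-5", "6-10", "11-20", "21-50", "51-100", ">100"),
             lower = c(2, 6, 11, 21, 51, 101),
             upper = c(5, 10, 20, 50, 100, Inf),
             stringsAsFactors = FALSE)
}

validate_copy_bins <- function(bins) {
  if (!is.data.frame(bins) || !all(c("lower", "upper") %in% names(bins))) {
    stop("bins must be a data.frame with lower and upper columns",
         call. = FALSE)
  }
  n <- nrow(bins)
  ok <- n >= 1 && bins$lower[1] == 2 && is.infinite(bins$upper[n]) &&
    all(bins$upper >= bins$lower) &&
    (n == 1 || all(bins$lower[-1] == bins$upper[-n] + 1))
  if (!ok) {
    stop("bins must partition [2, Inf) without gaps or overlaps",
         call. = FALSE)
  }
  invisible(bins)
}

#' Copy-number distribution of a clean tag set
#'
#' Classifies clean tags by copy number and reports, per bin, the
#' fraction of distinct tags and the fraction of total copies.
#'
#' @param clean A `clean_tag_set`.
#' @param bins Copy-range partition of `[2, Inf)`; see
#'   [default_copy_bins()].
#' @return Data frame with columns `label`, `lower`, `upper`,
#'   `distinct_tags`, `total_copies`, `distinct_fraction`,
#'   `copy_fraction`. Both fraction columns sum to 1.
#' @export
copy_distribution <- function(clean, bins = default_copy_bins()) {
  stopifnot(inherits(clean, "clean_tag_set"))
  validate_copy_bins(bins)
  if (clean$distinct_clean == 0) {
    stop("copy_distribution() undefined for an empty clean tag set",
         call. = FALSE)
  }
  bin_idx <- findInterval(clean$counts, bins$lower)
  distinct_tags <- tabulate(bin_idx, nbins = nrow(bins))
  total_copies <- vapply(seq_len(nrow(bins)),
                         function(i) sum(clean$counts[bin_idx == i]),
                         numeric(1))
  data.frame(
    label = bins$label %||% paste0(bins$lower, "-", bins$upper),
    lower = bins$lower,
    upper = bins$upper,
    distinct_tags = distinct_tags,
    total_copies = total_copies,
    distinct_fraction = distinct_tags / sum(distinct_tags),
    copy_fraction = total_copies / sum(total_copies),
    stringsAsFactors = FALSE
  )
}

#' Read a tag/count TSV as a raw tag set
#'
#' Two-column TSV (`tag_seq`, `count`), with or without a header line.
#' 17-base tags are accepted and anchored with `CATG`.
#'
#' @param path TSV path.
#' @param library_id Library identifier.
#' @return A [raw_tag_set()].
#' @export
read_tag_counts <- function(path, library_id = "lib") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("tag", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE,
                   col.names = c("tag_seq", "count"))
  raw_tag_set(setNames(df$count, df$tag_seq), library_id)
}

#' Write a clean tag set as TSV
#' @param clean A `clean_tag_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clean_tags <- function(clean, path) {
  stopifnot(inherits(clean, "clean_tag_set"))
  write_tsv(data.frame(tag_seq = names(clean$counts),
                       count = as.vector(clean$counts)), path)
  invisible(path)
}

#' Read a clean tag set back from TSV
#' @param path TSV written by [write_clean_tags()].
#' @param library_id Library identifier.
#' @return A `clean_tag_set` (the removal ledger of the original run is
#'   not stored in the TSV and is re-initialised to zero).
#' @export
read_clean_tags <- function(path, library_id = "lib") {
  df <- read_tsv(path, colClasses = c("character", "numeric"))
  clean_tags(raw_tag_set(setNames(df$count, df$tag_seq), library_id))
}

#' Write the removal ledger as JSON
#' @param clean A `clean_tag_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_removal_ledger <- function(clean, path) {
  stopifnot(inherits(clean, "clean_tag_set"))
  jsonlite::write_json(list(
    library_id = clean$library_id,
    total_raw = clean$total_raw,
    distinct_raw = clean$distinct_raw,
    total_clean = clean$total_clean,
    distinct_clean = clean$distinct_clean,
    empty_reads = clean$empty_reads,
    removal_ledger = as.list(clean$removal_ledger)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
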