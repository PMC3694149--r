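# Shared constants and small helpers.

DNA_BASES <- c("A", "C", "G", "T")
TAG_ANCHOR <- "CATG"
TAG_LENGTH <- 21L            # 4-base anchor + 17-base variable region
VARIABLE_START <- 5L         # first variable-region position within a tag

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage rounded to two decimals
#'
#' The reporting convention used throughout the library summaries:
#' `100 * numerator / denominator`, rounded to two decimal places.
#'
#' @param numerator,denominator Numeric vectors; `denominator` must be
#'   strictly positive.
#' @return Numeric vector of percentages on the 0-100 scale.
#' @examples
#' report_percentage(39497, 49053)
#' @export
report_percentage <- function(numerator, denominator) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("report_percentage(): denominator must be positive", call. = FALSE)
  }
  round(100 * numerator / denominator, 2)
}

reverse_complement <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Sum counts over duplicate tag sequences; returns a named numeric vector.
aggregate_tag_counts <- function(tag_seq, counts) {
  if (!length(tag_seq)) return(setNames(numeric(0), character(0)))
  agg <- rowsum(as.numeric(counts), tag_seq)
  setNames(as.vector(agg), rownames(agg))
}

random_dna <- function(n_chars) {
  paste(sample(DNA_BASES, n_chars, replace = TRUE), collapse = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
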