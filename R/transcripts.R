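# Transcript reference input: multi-FASTA or in-memory data frame.

#' Read a transcript reference from FASTA
#'
#' Reads a (wrapped or unwrapped) multi-FASTA file of transcript sequences.
#' The gene identifier is the header token before the first whitespace; the
#' remainder of the description line is ignored. Sequences are upper-cased
#' and must use only the `A`, `C`, `G`, `T`, `N` alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `gene_id` and `sequence`.
#' @seealso [build_virtual_tag_index()]
#' @export
read_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as_transcripts(data.frame(
    gene_id = sub("\\s.*$", "", names(ss)),
    sequence = toupper(as.character(ss)),
    stringsAsFactors = FALSE
  ))
}

#' Validate a transcript table
#'
#' @param x A data frame with character columns `gene_id` and `sequence`.
#' @return The validated data frame (row names dropped).
#' @export
as_transcripts <- function(x) {
  if (!is.data.frame(x) || !all(c("gene_id", "sequence") %in% names(x))) {
    stop("transcripts must be a data.frame with gene_id and sequence columns",
         call. = FALSE)
  }
  x <- data.frame(gene_id = as.character(x$gene_id),
                  sequence = toupper(as.character(x$sequence)),
                  stringsAsFactors = FALSE)
  if (anyNA(x$gene_id) || any(!nzchar(x$gene_id))) {
    stop("gene_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene_id in reference: ",
         paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", x$sequence)
  if (any(bad)) {
    stop("sequence characters outside {A,C,G,T,N} for: ",
         paste(head(x$gene_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Write a transcript table to FASTA
#'
#' @param transcripts A transcript data frame (see [as_transcripts()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  tr <- as_transcripts(transcripts)
  ss <- Biostrings::DNAStringSet(tr$sequence)
  names(ss) <- tr$gene_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
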