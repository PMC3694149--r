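# Virtual tag reference: CATG-anchored 21-base tags enumerated from both
# strands of every transcript. Tag chemistry: the restriction enzyme
# recognises CATG and its coupled type IIS enzyme cuts 17 bp downstream,
# so each eligible site yields anchor + 17 variable bases.

# Enumerate tags on one strand. `seqs` are already oriented (the caller
# passes the reverse complement for the antisense strand). site_rank is 1
# for the 3'-most site with a full 17-base downstream run on that strand;
# tags whose variable region contains N are suppressed after ranking.
scan_strand <- function(gene_ids, seqs, strand) {
  empty <- data.frame(tag_seq = character(0), gene_id = character(0),
                      strand = character(0), site_rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  hits <- gregexpr(TAG_ANCHOR, seqs, fixed = TRUE)
  nh <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), integer(1))
  if (!any(nh > 0L)) return(empty)
  keep_tr <- nh > 0L
  pos <- unlist(hits[keep_tr], use.names = FALSE)
  gene <- rep(gene_ids[keep_tr], nh[keep_tr])
  seqr <- rep(seqs[keep_tr], nh[keep_tr])
  full <- pos + TAG_LENGTH - 1L <= nchar(seqr)
  if (!any(full)) return(empty)
  pos <- pos[full]; gene <- gene[full]; seqr <- seqr[full]
  tag <- substring(seqr, pos, pos + TAG_LENGTH - 1L)
  # rank among full-length sites, 3'-most first (largest position = rank 1)
  rank3 <- stats::ave(pos, gene, FUN = function(p) rank(-p, ties.method = "first"))
  ok <- !grepl("N", tag, fixed = TRUE)
  data.frame(tag_seq = tag[ok], gene_id = gene[ok],
             strand = rep(strand, sum(ok)),
             site_rank = as.integer(rank3[ok]), stringsAsFactors = FALSE)
}

# Pre-hash lookup tables: unique tag sequences with their distinct gene sets.
build_index_lookup <- function(tags) {
  if (!nrow(tags)) {
    return(list(utags = character(0), genes = list(),
                gene1 = character(0), multi = logical(0),
                genes_csv = character(0)))
  }
  pair_key <- paste(tags$tag_seq, tags$gene_id, sep = "\r")
  first <- !duplicated(pair_key)
  ts <- tags$tag_seq[first]
  gs <- tags$gene_id[first]
  o <- order(ts, gs, method = "radix")
  ts <- ts[o]; gs <- gs[o]
  genes <- split(gs, factor(ts, levels = unique(ts)))
  utags <- names(genes)
  ngene <- lengths(genes)
  list(
    utags = utags,
    genes = unname(genes),
    gene1 = vapply(genes, `[`, character(1), 1L, USE.NAMES = FALSE),
    multi = ngene > 1L,
    genes_csv = vapply(genes, paste, character(1), collapse = ",",
                       USE.NAMES = FALSE)
  )
}

#' Build the virtual tag index from a transcript reference
#'
#' Enumerates every CATG-anchored 21-base virtual tag on the sense strand
#' and on the reverse complement (antisense strand) of each transcript.
#' A site only yields a tag when at least 17 bases follow the anchor;
#' overlapping sites are all enumerated; tags containing `N` are dropped.
#' `site_rank` is 1 for the 3'-most eligible site on its strand.
#'
#' @param transcripts A transcript data frame (see [as_transcripts()]) or
#'   the result of [read_transcripts()].
#' @return An object of class `virtual_tag_index`: a list with `tags`
#'   (data frame `tag_seq`, `gene_id`, `strand`, `site_rank`), `n_genes`,
#'   `n_catg_genes` (genes contributing at least one tag on either strand)
#'   and `gene_ids`.
#' @examples
#' tr <- data.frame(gene_id = "g1",
#'                  sequence = "GGCATGAAAAAAAAAAAAAAAAAGG")
#' idx <- build_virtual_tag_index(tr)
#' idx$tags
#' @export
build_virtual_tag_index <- function(transcripts) {
  tr <- as_transcripts(transcripts)
  sense <- scan_strand(tr$gene_id, tr$sequence, "sense")
  anti <- scan_strand(tr$gene_id, reverse_complement(tr$sequence), "antisense")
  tags <- rbind(sense, anti)
  idx <- list(
    tags = tags,
    n_genes = nrow(tr),
    n_catg_genes = length(unique(tags$gene_id)),
    gene_ids = tr$gene_id,
    lookup = build_index_lookup(tags)
  )
  class(idx) <- "virtual_tag_index"
  idx
}

#' @export
print.virtual_tag_index <- function(x, ...) {
  cat("Virtual tag index:", nrow(x$tags), "tags from", x$n_catg_genes,
      "of", x$n_genes, "genes\n")
  if (x$n_genes > 0) {
    cat("CATG-site gene percentage:", catg_gene_percentage(x), "\n")
  }
  invisible(x)
}

#' Percentage of reference genes with an indexable CATG site
#'
#' @param index A `virtual_tag_index`.
#' @return `100 * n_catg_genes / n_genes`, rounded to two decimals.
#' @export
catg_gene_percentage <- function(index) {
  stopifnot(inherits(index, "virtual_tag_index"))
  if (index$n_genes == 0) {
    stop("catg_gene_percentage() undefined for an empty reference",
         call. = FALSE)
  }
  report_percentage(index$n_catg_genes, index$n_genes)
}

#' Serialize a virtual tag index
#'
#' Writes the tag table as TSV (`tag_seq`, `gene_id`, `strand`,
#' `site_rank`) and a JSON stats block (`n_genes`, `n_catg_genes`,
#' `catg_gene_percentage`, `gene_ids`).
#'
#' @param index A `virtual_tag_index`.
#' @param tsv_path Output TSV path.
#' @param stats_path Output JSON path (optional).
#' @return `tsv_path`, invisibly.
#' @export
write_virtual_tag_index <- function(index, tsv_path, stats_path = NULL) {
  stopifnot(inherits(index, "virtual_tag_index"))
  write_tsv(index$tags, tsv_path)
  if (!is.null(stats_path)) {
    stats <- list(
      n_genes = index$n_genes,
      n_catg_genes = index$n_catg_genes,
      catg_gene_percentage =
        if (index$n_genes > 0) catg_gene_percentage(index) else NA,
      gene_ids = index$gene_ids
    )
    jsonlite::write_json(stats, stats_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Read back a serialized virtual tag index
#'
#' @param tsv_path Tag table TSV written by [write_virtual_tag_index()].
#' @param stats_path Matching JSON stats block.
#' @return A `virtual_tag_index`.
#' @export
read_virtual_tag_index <- function(tsv_path, stats_path) {
  tags <- read_tsv(tsv_path,
                   colClasses = c("character", "character", "character",
                                  "integer"))
  stats <- jsonlite::read_json(stats_path, simplifyVector = TRUE)
  idx <- list(
    tags = tags,
    n_genes = as.integer(stats$n_genes),
    n_catg_genes = as.integer(stats$n_catg_genes),
    gene_ids = as.character(stats$gene_ids),
    lookup = build_index_lookup(tags)
  )
  class(idx) <- "virtual_tag_index"
  idx
}
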