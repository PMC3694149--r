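# Tag-to-gene mapping against the virtual tag index.
#
# Exact matches take precedence; otherwise the 3 x 17 = 51 single-base
# substitution neighborhood of the variable region is looked up (the
# 4-base anchor is chemically fixed, so mismatches are confined to the
# variable region). The distinct gene set at the chosen mismatch level
# determines the verdict: one gene -> unambiguous, several -> ambiguous
# (filtered from gene-level counting), none -> unknown. Multiple sites or
# strands of the SAME gene never create ambiguity.

#' Map clean tags to genes
#'
#' @param clean A `clean_tag_set` of canonical 21-base tags.
#' @param index A `virtual_tag_index`.
#' @param max_mismatch Mismatch budget, 0 or 1.
#' @return Data frame with one row per distinct clean tag: `tag_seq`,
#'   `status` (`unambiguous`/`ambiguous`/`unknown`), `gene_id` (only for
#'   unambiguous tags), `mismatches` (0 or 1; `NA` for unknown), `genes`
#'   (comma-joined distinct candidate genes at the chosen mismatch level)
#'   and `copies`.
#' @export
map_tags <- function(clean, index, max_mismatch = 1L) {
  stopifnot(inherits(clean, "clean_tag_set"),
            inherits(index, "virtual_tag_index"))
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  qt <- names(clean$counts)
  n <- length(qt)
  status <- rep("unknown", n)
  gene <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  genes_csv <- rep(NA_character_, n)
  lk <- index$lookup

  ex <- match(qt, lk$utags)
  hit <- which(!is.na(ex))
  if (length(hit)) {
    ei <- ex[hit]
    status[hit] <- ifelse(lk$multi[ei], "ambiguous", "unambiguous")
    gene[hit[!lk$multi[ei]]] <- lk$gene1[ei[!lk$multi[ei]]]
    genes_csv[hit] <- lk$genes_csv[ei]
    mism[hit] <- 0L
  }

  if (max_mismatch >= 1L && n > length(hit) && length(lk$utags)) {
    need <- which(is.na(ex))
    qn <- qt[need]
    hq <- vector("list", 4L * (TAG_LENGTH - VARIABLE_START + 1L))
    hu <- hq
    k <- 0L
    for (p in VARIABLE_START:TAG_LENGTH) {
      for (b in DNA_BASES) {
        v <- qn
        substr(v, p, p) <- b
        m <- match(v, lk$utags)
        f <- which(!is.na(m))
        if (length(f)) {
          k <- k + 1L
          hq[[k]] <- need[f]
          hu[[k]] <- m[f]
        }
      }
    }
    if (k) {
      q <- unlist(hq[seq_len(k)], use.names = FALSE)
      u <- unlist(hu[seq_len(k)], use.names = FALSE)
      gl <- lk$genes[u]
      qq <- rep(q, lengths(gl))
      gg <- unlist(gl, use.names = FALSE)
      keep <- !duplicated(paste(qq, gg, sep = "\r"))
      qq <- qq[keep]
      gg <- gg[keep]
      ngene <- tabulate(qq, nbins = n)
      one <- which(ngene == 1L)
      many <- which(ngene > 1L)
      status[one] <- "unambiguous"
      status[many] <- "ambiguous"
      mism[ngene > 0L] <- 1L
      gene[one] <- gg[match(one, qq)]
      sp <- split(gg, qq)
      genes_csv[as.integer(names(sp))] <-
        vapply(sp, paste, character(1), collapse = ",")
    }
  }

  data.frame(tag_seq = qt, status = status, gene_id = gene,
             mismatches = mism, genes = genes_csv,
             copies = as.vector(clean$counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Library summary over clean tags and their assignments
#'
#' Recreates the standard library categorisation table: clean totals,
#' all-mapped (unambiguous + ambiguous) and unambiguous copy/distinct
#' counts with percentages of the clean totals, gene counts with
#' percentages of the reference gene universe, and the unknown remainder.
#' Percentages follow [report_percentage()] (two decimals).
#'
#' @param clean A `clean_tag_set` with a positive clean total.
#' @param assignments Output of [map_tags()] covering all distinct clean
#'   tags.
#' @param index The `virtual_tag_index` used for mapping (supplies the
#'   reference gene universe).
#' @return An object of class `library_summary` (a named list).
#' @export
summarize_library <- function(clean, assignments, index) {
  stopifnot(inherits(clean, "clean_tag_set"),
            inherits(index, "virtual_tag_index"))
  if (clean$total_clean <= 0) {
    stop("summarize_library() undefined for a zero clean total",
         call. = FALSE)
  }
  if (!setequal(assignments$tag_seq, names(clean$counts))) {
    stop("assignments must cover all distinct clean tags", call. = FALSE)
  }
  copies <- assignments$copies
  mapped <- assignments$status != "unknown"
  unamb <- assignments$status == "unambiguous"
  all_total <- sum(copies[mapped])
  all_distinct <- sum(mapped)
  un_total <- sum(copies[unamb])
  un_distinct <- sum(unamb)
  all_genes <- unique(unlist(strsplit(assignments$genes[mapped], ",",
                                      fixed = TRUE)))
  un_genes <- unique(assignments$gene_id[unamb])
  ct <- clean$total_clean
  dc <- clean$distinct_clean
  pct_or_zero <- function(num, den) if (den > 0) report_percentage(num, den) else 0
  out <- list(
    library_id = clean$library_id,
    clean_total = ct,
    clean_distinct = dc,
    all_mapped_total = all_total,
    all_mapped_total_pct = report_percentage(all_total, ct),
    all_mapped_distinct = all_distinct,
    all_mapped_distinct_pct = report_percentage(all_distinct, dc),
    unambiguous_total = un_total,
    unambiguous_total_pct = report_percentage(un_total, ct),
    unambiguous_distinct = un_distinct,
    unambiguous_distinct_pct = report_percentage(un_distinct, dc),
    all_mapped_genes = length(all_genes),
    all_mapped_genes_pct = pct_or_zero(length(all_genes), index$n_genes),
    unambiguous_genes = length(un_genes),
    unambiguous_genes_pct = pct_or_zero(length(un_genes), index$n_genes),
    unknown_total = ct - all_total,
    unknown_total_pct = report_percentage(ct - all_total, ct),
    unknown_distinct = dc - all_distinct,
    unknown_distinct_pct = report_percentage(dc - all_distinct, dc)
  )
  class(out) <- "library_summary"
  out
}

#' @export
print.library_summary <- function(x, ...) {
  cat("Library", x$library_id, "\n")
  cat(sprintf("  clean: %s copies / %s distinct\n",
              format(x$clean_total, big.mark = ","),
              format(x$clean_distinct, big.mark = ",")))
  cat(sprintf("  all mapped: %s (%.2f%%) copies, %s (%.2f%%) distinct\n",
              format(x$all_mapped_total, big.mark = ","),
              x$all_mapped_total_pct,
              format(x$all_mapped_distinct, big.mark = ","),
              x$all_mapped_distinct_pct))
  cat(sprintf("  unambiguous: %s (%.2f%%) copies, genes: %d (%.2f%%)\n",
              format(x$unambiguous_total, big.mark = ","),
              x$unambiguous_total_pct, x$unambiguous_genes,
              x$unambiguous_genes_pct))
  cat(sprintf("  unknown: %s (%.2f%%) copies\n",
              format(x$unknown_total, big.mark = ","), x$unknown_total_pct))
  invisible(x)
}

#' Arrange library summaries as a table
#'
#' One row per summary field, one column per library, in the standard
#' categorisation-table order.
#'
#' @param summaries List of `library_summary` objects.
#' @return Data frame with a `field` column and one column per library.
#' @export
summary_table <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  fields <- setdiff(names(summaries[[1]]), "library_id")
  out <- data.frame(field = fields, stringsAsFactors = FALSE)
  for (s in summaries) {
    out[[s$library_id]] <- unlist(s[fields], use.names = FALSE)
  }
  out
}

#' Write a tag assignment table as TSV
#' @param assignments Output of [map_tags()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(assignments, path)
  invisible(path)
}

#' Read a tag assignment table from TSV
#' @param path TSV written by [write_assignments()].
#' @return Assignment data frame.
#' @export
read_assignments <- function(path) {
  read_tsv(path, colClasses = c("character", "character", "character",
                                "integer", "character", "numeric"),
           na.strings = "NA")
}
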