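# Per-gene quantification in tag copies per million clean tags (TPM).
#
# TPM here is the tag-profiling unit: unambiguous tag copies scaled per
# million CLEAN tags (the denominator is the clean total of the library,
# not the mapped total, and no transcript-length normalisation applies
# because the chemistry anchors one tag at the 3'-most restriction site).

#' Per-gene unambiguous tag copies
#'
#' @param assignments Output of [map_tags()].
#' @return Named numeric vector: gene_id -> unambiguous copy total.
#' @export
gene_counts <- function(assignments) {
  un <- assignments$status == "unambiguous"
  if (!any(un)) return(setNames(numeric(0), character(0)))
  aggregate_tag_counts(assignments$gene_id[un], assignments$copies[un])
}

#' TPM for one library
#'
#' @param gene_counts Named numeric vector of per-gene copies (>= 0).
#' @param clean_total Clean tag total of the library (> 0).
#' @return Data frame `gene_id`, `count`, `tpm`, `detected`
#'   (`count >= 1`).
#' @examples
#' compute_tpm(c(g1 = 10), clean_total = 1e6)  # TPM 10
#' @export
compute_tpm <- function(gene_counts, clean_total) {
  if (!is.numeric(clean_total) || length(clean_total) != 1 ||
      clean_total <= 0) {
    stop("clean_total must be a single positive number", call. = FALSE)
  }
  if (any(gene_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  data.frame(gene_id = names(gene_counts),
             count = as.vector(gene_counts),
             tpm = as.vector(gene_counts) * 1e6 / clean_total,
             detected = as.vector(gene_counts) >= 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multi-library expression table
#'
#' @param count_list Named list (library_id -> named per-gene copy
#'   vector, as from [gene_counts()]).
#' @param clean_totals Named numeric vector of clean totals per library.
#' @return An object of class `expression_table`: `genes`, `libraries`,
#'   `counts` and `tpm` (genes x libraries matrices), `clean_totals`.
#' @export
expression_table <- function(count_list, clean_totals) {
  stopifnot(length(count_list) >= 1,
            !is.null(names(count_list)),
            all(names(count_list) %in% names(clean_totals)))
  if (any(clean_totals[names(count_list)] <= 0)) {
    stop("clean totals must be positive", call. = FALSE)
  }
  libs <- names(count_list)
  genes <- sort(unique(unlist(lapply(count_list, names), use.names = FALSE)))
  counts <- matrix(0, nrow = length(genes), ncol = length(libs),
                   dimnames = list(genes, libs))
  for (lib in libs) {
    v <- count_list[[lib]]
    counts[names(v), lib] <- v
  }
  totals <- clean_totals[libs]
  tpm <- sweep(counts, 2L, totals / 1e6, "/")
  structure(list(genes = genes, libraries = libs, counts = counts,
                 tpm = tpm, clean_totals = totals),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("Expression table:", length(x$genes), "genes x",
      length(x$libraries), "libraries\n")
  cat("Clean totals:",
      paste(x$libraries, format(x$clean_totals, big.mark = ","),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Detection overlap across libraries
#'
#' Set-algebra report over detected genes: per-library detected counts,
#' the intersection over all libraries, and per-library exclusive counts
#' (genes detected in exactly that library).
#'
#' @param expr An `expression_table` covering at least two libraries.
#' @param min_count Detection threshold on copies (default 1).
#' @return List with `detected`, `intersection`, `exclusive`,
#'   `min_count`.
#' @export
overlap_report <- function(expr, min_count = 1) {
  stopifnot(inherits(expr, "expression_table"))
  if (length(expr$libraries) < 2) {
    stop("overlap_report() needs at least two libraries", call. = FALSE)
  }
  det <- expr$counts >= min_count
  nlib_det <- rowSums(det)
  exclusive <- colSums(det & nlib_det == 1L)
  list(detected = colSums(det),
       intersection = sum(nlib_det == ncol(det)),
       exclusive = exclusive,
       min_count = min_count)
}

#' Write an expression table as TSV
#'
#' Long-to-wide genes x libraries layout with `count_` and `tpm_`
#' column pairs per library.
#'
#' @param expr An `expression_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(gene_id = expr$genes, stringsAsFactors = FALSE)
  for (lib in expr$libraries) {
    df[[paste0("count_", lib)]] <- expr$counts[, lib]
    df[[paste0("tpm_", lib)]] <- expr$tpm[, lib]
  }
  write_tsv(df, path)
  invisible(path)
}

#' Read an expression table from TSV
#'
#' @param path TSV written by [write_expression_table()].
#' @param clean_totals Named clean totals per library (recomputes TPM
#'   consistently with the stored counts).
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path, clean_totals) {
  df <- read_tsv(path)
  libs <- sub("^count_", "", grep("^count_", names(df), value = TRUE))
  count_list <- lapply(libs, function(lib) {
    setNames(df[[paste0("count_", lib)]], df$gene_id)
  })
  names(count_list) <- libs
  expression_table(count_list, clean_totals)
}
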