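# Sequencing-saturation analysis and consolidated run reports.

#' Sequencing saturation curve
#'
#' Detected-gene count as a function of sampled sequencing depth. A
#' single seeded random permutation of all clean tag copies is drawn and
#' detection at depth `d` counts the genes whose first unambiguously
#' assigned copy falls within the first `d` copies. Nested subsampling
#' makes the curve monotone by construction, each depth marginally equals
#' a without-replacement subsample, and the final grid point reproduces
#' full-depth detection exactly.
#'
#' @param clean A `clean_tag_set`.
#' @param assignments Output of [map_tags()] for `clean`.
#' @param grid Ascending depths; the last must equal the clean total.
#'   Default: 20 evenly spaced depths ending at full depth.
#' @param seed Integer seed for the permutation.
#' @return An object of class `saturation_curve`: list with `points`
#'   (data frame `tags_sampled`, `genes_detected`) and `seed`.
#' @export
saturation_curve <- function(clean, assignments, grid = NULL, seed = 1L) {
  stopifnot(inherits(clean, "clean_tag_set"))
  total <- clean$total_clean
  if (is.null(grid)) grid <- round(seq_len(20L) / 20 * total)
  grid <- as.numeric(grid)
  if (any(diff(grid) < 0)) stop("grid must be ascending", call. = FALSE)
  if (any(grid < 0) || any(grid > total)) {
    stop("grid depths must lie in [0, total_clean]", call. = FALSE)
  }
  if (length(grid) && grid[length(grid)] != total) {
    stop("last grid depth must equal the clean total", call. = FALSE)
  }
  un <- assignments$status == "unambiguous"
  gene_f <- factor(assignments$gene_id[un])
  copies_un <- assignments$copies[un]
  # owner label per copy: gene index for unambiguous copies, 0 otherwise
  owner <- c(rep.int(as.integer(gene_f), copies_un),
             integer(total - sum(copies_un)))
  set.seed(seed)
  perm <- sample(owner)
  first_pos <- which(!duplicated(perm))
  first_gene <- perm[first_pos]
  fp <- sort(first_pos[first_gene != 0L])
  points <- data.frame(tags_sampled = grid,
                       genes_detected = findInterval(grid, fp))
  structure(list(points = points, seed = seed), class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  n <- nrow(x$points)
  cat("Saturation curve (seed", paste0(x$seed, "):"), n, "depths,",
      x$points$genes_detected[n], "genes at full depth\n")
  invisible(x)
}

#' Assemble a consolidated run report
#'
#' Machine-readable bundle of all per-run summary surfaces. Missing
#' components yield explicit omission markers rather than errors, so a
#' partial run still produces a valid (partial) report.
#'
#' @param summaries Named list of `library_summary` objects (or `NULL`).
#' @param distributions Named list of [copy_distribution()] tables.
#' @param curves Named list of `saturation_curve` objects.
#' @param deg_summaries [deg_all_pairs()] summary data frame, requires
#'   at least two libraries.
#' @param overlap [overlap_report()] output.
#' @param config Configuration echo (any serialisable list).
#' @return An object of class `run_report` (nested list).
#' @export
render_run_report <- function(summaries = NULL, distributions = NULL,
                              curves = NULL, deg_summaries = NULL,
                              overlap = NULL, config = NULL) {
  omit <- function(what) list(omitted = TRUE, reason = paste(what, "not supplied"))
  bundle <- list(
    version = as.character(packageVersion("tagdge")),
    config = config %||% list(),
    libraries = if (is.null(summaries)) omit("library summaries") else
      lapply(summaries, unclass),
    copy_distributions = if (is.null(distributions)) omit("copy distributions") else
      distributions,
    saturation = if (is.null(curves)) omit("saturation curves") else
      lapply(curves, function(cv) list(seed = cv$seed, points = cv$points)),
    overlap = if (is.null(overlap)) omit("overlap report") else overlap,
    deg = if (is.null(deg_summaries)) omit("DEG summaries (single-library run)") else
      deg_summaries
  )
  class(bundle) <- "run_report"
  bundle
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report (tagdge", paste0(x$version, ")\n"))
  nlib <- if (isTRUE(x$libraries$omitted)) 0 else length(x$libraries)
  cat("  libraries:", nlib, "\n")
  if (!isTRUE(x$deg$omitted) && is.data.frame(x$deg)) {
    cat("  DEG pairs:", nrow(x$deg), "\n")
  } else {
    cat("  DEG section omitted\n")
  }
  invisible(x)
}

#' Write a run report bundle to disk
#'
#' Writes `report.json` plus human-readable TSVs: the library
#' categorisation table (`library_summaries.tsv`), the per-pair DEG
#' summary (`deg_summary.tsv`), and per-library copy-distribution and
#' saturation tables.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  if (!isTRUE(report$libraries$omitted) && length(report$libraries)) {
    sums <- lapply(report$libraries, function(s) {
      class(s) <- "library_summary"; s
    })
    write_tsv(summary_table(sums), file.path(dir, "library_summaries.tsv"))
  }
  if (!isTRUE(report$deg$omitted) && is.data.frame(report$deg)) {
    write_tsv(report$deg, file.path(dir, "deg_summary.tsv"))
  }
  if (!isTRUE(report$copy_distributions$omitted)) {
    for (lib in names(report$copy_distributions)) {
      write_tsv(report$copy_distributions[[lib]],
                file.path(dir, paste0("copy_distribution_", lib, ".tsv")))
    }
  }
  if (!isTRUE(report$saturation$omitted)) {
    for (lib in names(report$saturation)) {
      write_tsv(report$saturation[[lib]]$points,
                file.path(dir, paste0("saturation_", lib, ".tsv")))
    }
  }
  invisible(dir)
}
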