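# Pipeline orchestration: validated run configuration, file-mediated
# stages, and the end-to-end runner. Every stage reads and writes plain
# TSV/JSON intermediates in a fixed output-directory layout, so any
# stage can be re-run, inspected or replaced individually and a chain of
# per-stage invocations equals the end-to-end run.
#
# Layout under the output directory:
#   reference.fasta, truth.json            (simulate)
#   virtual_tags.tsv, reference_stats.json (build-ref)
#   <lib>/raw_tags.tsv                     (simulate or user input)
#   <lib>/clean_tags.tsv, removal_ledger.json, copy_distribution.tsv
#   <lib>/assignments.tsv, library_summary.json, saturation.tsv
#   expression.tsv, overlap.json           (quant)
#   deg_<A>_<B>.tsv, deg_summary.tsv       (deg)
#   report.json + report TSVs              (report)

#' Build a validated run configuration
#'
#' @param reference Path to a transcript FASTA (ignored when `simulate`
#'   is given; the simulated reference is used instead).
#' @param libraries List of library specs, each a list with `id`, `path`
#'   and `format` ("tsv" or "fastq"); ignored when `simulate` is given.
#' @param simulate Optional list of [simulate_study()] arguments for a
#'   fully synthetic run.
#' @param fdr_cutoff,min_abs_log2,tpm_floor DEG thresholds (defaults
#'   0.001, 1, 0.01).
#' @param max_mismatch Mapping mismatch budget, 0 or 1.
#' @param copy_bins Copy-number bins (default [default_copy_bins()]).
#' @param saturation_points Number of saturation grid depths.
#' @param adaptor Adaptor sequence trimmed from FASTQ reads.
#' @param seed Master seed.
#' @param out_dir Default output directory for [run_pipeline()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(reference = NULL, libraries = NULL, simulate = NULL,
                       fdr_cutoff = 0.001, min_abs_log2 = 1,
                       tpm_floor = 0.01, max_mismatch = 1L,
                       copy_bins = NULL, saturation_points = 20L,
                       adaptor = "", seed = 1L, out_dir = NULL) {
  cfg <- structure(list(
    reference = reference, libraries = libraries, simulate = simulate,
    fdr_cutoff = fdr_cutoff, min_abs_log2 = min_abs_log2,
    tpm_floor = tpm_floor, max_mismatch = as.integer(max_mismatch),
    copy_bins = copy_bins, saturation_points = as.integer(saturation_points),
    adaptor = adaptor, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks thresholds, the mismatch budget, bins and library specs before
#' any I/O happens; reports every offending field at once.
#'
#' @param config A `run_config` or plain list.
#' @return The validated `run_config`.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(config$fdr_cutoff) || config$fdr_cutoff <= 0 ||
      config$fdr_cutoff > 1) {
    problems <- c(problems, "fdr_cutoff must lie in (0, 1]")
  }
  if (!num1(config$min_abs_log2) || config$min_abs_log2 < 0) {
    problems <- c(problems, "min_abs_log2 must be >= 0")
  }
  if (!num1(config$tpm_floor) || config$tpm_floor <= 0) {
    problems <- c(problems, "tpm_floor must be > 0")
  }
  if (!config$max_mismatch %in% c(0L, 1L)) {
    problems <- c(problems, "max_mismatch must be 0 or 1")
  }
  if (!num1(config$saturation_points) || config$saturation_points < 1) {
    problems <- c(problems, "saturation_points must be >= 1")
  }
  if (!is.null(config$copy_bins)) {
    ok <- tryCatch({ validate_copy_bins(as.data.frame(config$copy_bins)); TRUE },
                   error = function(e) FALSE)
    if (!ok) problems <- c(problems, "copy_bins must partition [2, Inf)")
  }
  if (is.null(config$simulate)) {
    if (is.null(config$reference)) {
      problems <- c(problems, "reference (or simulate block) required")
    }
    if (!length(config$libraries)) {
      problems <- c(problems, "libraries (or simulate block) required")
    } else {
      for (i in seq_along(config$libraries)) {
        spec <- config$libraries[[i]]
        if (is.null(spec$id) || is.null(spec$path)) {
          problems <- c(problems,
                        sprintf("libraries[[%d]] needs id and path", i))
        }
        fmt <- spec$format %||% "tsv"
        if (!fmt %in% c("tsv", "fastq")) {
          problems <- c(problems,
                        sprintf("libraries[[%d]] format must be tsv or fastq", i))
        }
      }
    }
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(config) <- "run_config"
  config
}

#' Load a run configuration from JSON or YAML
#'
#' @param path Config file; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  defaults <- list(fdr_cutoff = 0.001, min_abs_log2 = 1, tpm_floor = 0.01,
                   max_mismatch = 1L, saturation_points = 20L,
                   adaptor = "", seed = 1L)
  cfg <- modifyList(defaults, raw[!vapply(raw, is.null, logical(1))])
  # resolve input paths relative to the config file's directory
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  cfg$reference <- resolve(cfg$reference)
  if (!is.null(cfg$libraries)) {
    cfg$libraries <- lapply(cfg$libraries, function(s) {
      s$path <- resolve(s$path)
      s
    })
  }
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

log_stage <- function(...) message("[tagdge] ", ...)

lib_dir <- function(dir, lib) {
  d <- file.path(dir, lib)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# ---- file-mediated stages -------------------------------------------------

stage_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  args <- config$simulate %||% list()
  args$seed <- args$seed %||% config$seed
  study <- do.call(simulate_study, args)
  write_transcripts_fasta(study$transcripts, file.path(dir, "reference.fasta"))
  write_simulation_truth(study$truth, file.path(dir, "truth.json"))
  for (lib in names(study$libraries)) {
    raw <- study$libraries[[lib]]
    write_tsv(data.frame(tag_seq = names(raw$counts),
                         count = as.vector(raw$counts)),
              file.path(lib_dir(dir, lib), "raw_tags.tsv"))
  }
  log_stage("simulate: ", length(study$libraries), " libraries, ",
            nrow(study$transcripts), " genes")
  invisible(names(study$libraries))
}

stage_build_ref <- function(dir, reference = file.path(dir, "reference.fasta")) {
  if (!file.exists(reference)) {
    stop("missing input file: ", reference, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- build_virtual_tag_index(read_transcripts(reference))
  write_virtual_tag_index(index, file.path(dir, "virtual_tags.tsv"),
                          file.path(dir, "reference_stats.json"))
  log_stage("build-ref: ", index$n_catg_genes, "/", index$n_genes,
            " genes with CATG sites (",
            if (index$n_genes) catg_gene_percentage(index) else 0, "%)")
  invisible(index)
}

stage_clean <- function(dir, lib, config = run_config(simulate = list())) {
  d <- lib_dir(dir, lib)
  spec <- NULL
  for (s in config$libraries %||% list()) if (identical(s$id, lib)) spec <- s
  raw <- if (!is.null(spec)) {
    if (!file.exists(spec$path)) {
      stop("missing input file: ", spec$path, call. = FALSE)
    }
    if (identical(spec$format %||% "tsv", "fastq")) {
      extract_raw_tags(read_fastq_sequences(spec$path), config$adaptor, lib)
    } else {
      read_tag_counts(spec$path, lib)
    }
  } else {
    read_tag_counts(file.path(d, "raw_tags.tsv"), lib)
  }
  clean <- clean_tags(raw)
  write_clean_tags(clean, file.path(d, "clean_tags.tsv"))
  write_removal_ledger(clean, file.path(d, "removal_ledger.json"))
  bins <- if (is.null(config$copy_bins)) default_copy_bins() else
    as.data.frame(config$copy_bins)
  write_tsv(copy_distribution(clean, bins),
            file.path(d, "copy_distribution.tsv"))
  log_stage("clean ", lib, ": ", clean$total_clean, " clean / ",
            clean$total_raw, " raw copies, ", clean$distinct_clean,
            " distinct")
  invisible(clean)
}

stage_map <- function(dir, lib, config = run_config(simulate = list())) {
  d <- lib_dir(dir, lib)
  index <- read_virtual_tag_index(file.path(dir, "virtual_tags.tsv"),
                                  file.path(dir, "reference_stats.json"))
  clean <- read_clean_tags(file.path(d, "clean_tags.tsv"), lib)
  assignments <- map_tags(clean, index, config$max_mismatch)
  write_assignments(assignments, file.path(d, "assignments.tsv"))
  summ <- summarize_library(clean, assignments, index)
  jsonlite::write_json(unclass(summ), file.path(d, "library_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  grid <- round(seq_len(config$saturation_points) /
                  config$saturation_points * clean$total_clean)
  curve <- saturation_curve(clean, assignments, grid,
                            seed = config$seed + sum(utf8ToInt(lib)))
  write_tsv(curve$points, file.path(d, "saturation.tsv"))
  log_stage("map ", lib, ": ", summ$unambiguous_genes,
            " unambiguous tag-mapped genes (",
            summ$unambiguous_total_pct, "% of clean copies)")
  invisible(list(assignments = assignments, summary = summ, curve = curve))
}

read_library_summary <- function(dir, lib) {
  s <- jsonlite::read_json(file.path(dir, lib, "library_summary.json"),
                           simplifyVector = TRUE)
  class(s) <- "library_summary"
  s
}

stage_quant <- function(dir, libs, config = run_config(simulate = list())) {
  count_list <- list()
  totals <- numeric(0)
  for (lib in libs) {
    d <- file.path(dir, lib)
    assignments <- read_assignments(file.path(d, "assignments.tsv"))
    clean <- read_clean_tags(file.path(d, "clean_tags.tsv"), lib)
    count_list[[lib]] <- gene_counts(assignments)
    totals[lib] <- clean$total_clean
  }
  expr <- expression_table(count_list, totals)
  write_expression_table(expr, file.path(dir, "expression.tsv"))
  if (length(libs) >= 2) {
    jsonlite::write_json(overlap_report(expr),
                         file.path(dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_stage("quant: ", length(expr$genes), " genes x ", length(libs),
            " libraries")
  invisible(expr)
}

stage_deg <- function(dir, libs, config = run_config(simulate = list())) {
  totals <- numeric(0)
  for (lib in libs) {
    totals[lib] <- read_clean_tags(file.path(dir, lib, "clean_tags.tsv"),
                                   lib)$total_clean
  }
  expr <- read_expression_table(file.path(dir, "expression.tsv"), totals)
  degs <- deg_all_pairs(expr, config$fdr_cutoff, config$min_abs_log2,
                        config$tpm_floor)
  for (pr in degs$pairs) {
    ab <- strsplit(pr$summary$pair, ":", fixed = TRUE)[[1]]
    write_tsv(pr$records,
              file.path(dir, paste0("deg_", ab[1], "_", ab[2], ".tsv")))
  }
  write_tsv(degs$summary, file.path(dir, "deg_summary.tsv"))
  log_stage("deg: ", sum(degs$summary$total), " significant calls over ",
            nrow(degs$summary), " pairs")
  invisible(degs)
}

stage_report <- function(dir, libs, config = run_config(simulate = list())) {
  summaries <- lapply(libs, function(lib) read_library_summary(dir, lib))
  names(summaries) <- libs
  distributions <- lapply(libs, function(lib) {
    read_tsv(file.path(dir, lib, "copy_distribution.tsv"))
  })
  names(distributions) <- libs
  curves <- lapply(libs, function(lib) {
    structure(list(points = read_tsv(file.path(dir, lib, "saturation.tsv")),
                   seed = config$seed), class = "saturation_curve")
  })
  names(curves) <- libs
  deg_path <- file.path(dir, "deg_summary.tsv")
  deg_summ <- if (file.exists(deg_path)) read_tsv(deg_path) else NULL
  ov_path <- file.path(dir, "overlap.json")
  overlap <- if (file.exists(ov_path)) {
    jsonlite::read_json(ov_path, simplifyVector = TRUE)
  } else NULL
  cfg_echo <- unclass(config)
  cfg_echo$copy_bins <- NULL
  report <- render_run_report(summaries, distributions, curves, deg_summ,
                              overlap, config = cfg_echo)
  write_report_bundle(report, dir)
  log_stage("report written to ", dir)
  invisible(report)
}

#' Run the complete pipeline
#'
#' Validates the configuration before any I/O, then executes
#' build-ref, clean, map, quant, deg and report (preceded by simulate
#' for synthetic runs), writing every intermediate under `out_dir`.
#' Reruns with the same configuration and seed are byte-identical.
#'
#' @param config A `run_config` (or path to a JSON/YAML config file).
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, a list with `index`, `summaries`, `expr`, `degs`,
#'   `report`, `libs` and `dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  config <- validate_run_config(config)
  dir <- out_dir %||% config$out_dir
  if (is.null(dir)) stop("out_dir required", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    libs <- stage_simulate(config, dir)
    reference <- file.path(dir, "reference.fasta")
  } else {
    libs <- vapply(config$libraries, function(s) s$id, character(1))
    reference <- config$reference
  }
  index <- stage_build_ref(dir, reference)
  for (lib in libs) stage_clean(dir, lib, config)
  mapped <- lapply(libs, function(lib) stage_map(dir, lib, config))
  names(mapped) <- libs
  expr <- stage_quant(dir, libs, config)
  degs <- if (length(libs) >= 2) stage_deg(dir, libs, config) else NULL
  report <- stage_report(dir, libs, config)
  invisible(list(index = index,
                 summaries = lapply(mapped, `[[`, "summary"),
                 expr = expr, degs = degs, report = report,
                 libs = libs, dir = dir))
}
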