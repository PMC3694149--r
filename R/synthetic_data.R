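# Seeded synthetic-data generator: transcriptomes, stage-wise expression
# truths, and error-injected raw tag libraries with planted ground truth.
#
# The generator emulates the data regime of a four-stage tag-profiling
# study: ~4.75 million tags per library, a transcript set in which about
# 80% of genes carry an indexable CATG site, a heavy-tailed per-gene
# copy-number law, and a subset of genes with stage-wise fold changes.
# Each library draws tag copies multinomially over the 3'-most
# sense-strand virtual tags, then reallocates copies into single-base
# substitution errors, N-containing copies, and random artifact tags;
# totals stay exact.

#' Simulate a transcript reference
#'
#' Gene sequences are iid uniform over A/C/G/T with lengths uniform on
#' `length_range`; deterministic given `seed`.
#'
#' @param n_genes Number of genes (>= 0).
#' @param length_range Two-element inclusive range of transcript lengths.
#' @param seed Integer seed.
#' @return A transcript data frame (`gene_id`, `sequence`).
#' @export
simulate_transcriptome <- function(n_genes, length_range = c(250L, 580L),
                                   seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 0) {
    stop("n_genes must be a single non-negative number", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  if (n_genes == 0) {
    return(data.frame(gene_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  len_choices <- seq.int(length_range[1], length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n_genes,
                                 replace = TRUE)]
  pool <- sample(DNA_BASES, sum(lens), replace = TRUE)
  big <- paste(pool, collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  data.frame(gene_id = gene_ids,
             sequence = substring(big, starts, ends),
             stringsAsFactors = FALSE)
}

#' Simulate a stage-wise expression truth
#'
#' Baseline gene proportions follow a heavy-tailed log-normal law (so
#' library copy distributions reproduce the dominant 2-5-copy regime of
#' shallow genes). A `de_fraction` subset of genes receives a stage-wise
#' step change: from a uniformly chosen onset stage (2..n_stages) onward
#' the gene's proportion is multiplied (or divided, with probability 1/2)
#' by a fold drawn from `fold_levels`. Stage proportions are renormalised
#' to the simplex.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param de_fraction Fraction of genes with a planted fold change.
#' @param fold_levels Candidate fold multipliers (> 0 and != 1).
#' @param sdlog Log-normal shape of baseline proportions.
#' @param n_stages Number of developmental stages (libraries).
#' @param seed Integer seed.
#' @return An object of class `simulation_truth`: `seed`, `genes`
#'   (data frame `gene_id`, `baseline_prop`, `de_flag`, `fold`,
#'   `onset_stage`), `multipliers` and `stage_props` (genes x stages
#'   matrices; each stage column sums to 1), `params`.
#' @export
simulate_expression <- function(gene_ids, de_fraction = 0.15,
                                fold_levels = c(2, 4, 8), sdlog = 1.5,
                                n_stages = 4L, seed = 1L) {
  n <- length(gene_ids)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (de_fraction > 0 && !length(fold_levels)) {
    stop("fold_levels must be non-empty when de_fraction > 0",
         call. = FALSE)
  }
  if (length(fold_levels) && any(fold_levels <= 0 | fold_levels == 1)) {
    stop("fold_levels must be positive and different from 1",
         call. = FALSE)
  }
  set.seed(seed)
  w <- rlnorm(n, meanlog = 0, sdlog = sdlog)
  baseline <- w / sum(w)
  mult <- matrix(1, nrow = n, ncol = n_stages,
                 dimnames = list(gene_ids, paste0("L", seq_len(n_stages))))
  n_de <- round(n * de_fraction)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  fold <- rep(NA_real_, n)
  onset <- rep(NA_integer_, n)
  if (length(de_idx) && n_stages < 2) {
    stop("planting stage-wise changes needs n_stages >= 2", call. = FALSE)
  }
  if (length(de_idx)) {
    # index-based draws: sample(x, ...) on a length-1 x would sample 1:x
    f <- fold_levels[sample.int(length(fold_levels), n_de, replace = TRUE)]
    up <- runif(n_de) < 0.5
    f[!up] <- 1 / f[!up]
    onset_choices <- seq.int(2L, n_stages)
    s <- onset_choices[sample.int(length(onset_choices), n_de,
                                  replace = TRUE)]
    fold[de_idx] <- f
    onset[de_idx] <- s
    for (k in seq_along(de_idx)) {
      mult[de_idx[k], s[k]:n_stages] <- f[k]
    }
  }
  stage_props <- mult * baseline
  stage_props <- sweep(stage_props, 2L, colSums(stage_props), "/")
  structure(list(
    seed = seed,
    genes = data.frame(gene_id = gene_ids, baseline_prop = baseline,
                       de_flag = seq_len(n) %in% de_idx,
                       fold = fold, onset_stage = onset,
                       stringsAsFactors = FALSE),
    multipliers = mult,
    stage_props = stage_props,
    params = list(de_fraction = de_fraction, fold_levels = fold_levels,
                  sdlog = sdlog, n_stages = n_stages)
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation truth:", nrow(x$genes), "genes,",
      ncol(x$stage_props), "stages,", sum(x$genes$de_flag),
      "DE genes (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

# Substitute a different base at one position of each tag, vectorised.
# `pos` and `alt` (1..3, index among the three non-matching bases) have
# one entry per tag.
substitute_base <- function(tags, pos, alt) {
  orig <- substring(tags, pos, pos)
  # column = original base, row = alternative index
  alt_tab <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"), nrow = 3)
  newb <- alt_tab[cbind(alt, match(orig, DNA_BASES))]
  for (p in unique(pos)) {
    i <- pos == p
    substr(tags[i], p, p) <- newb[i]
  }
  tags
}

#' Simulate one raw tag library
#'
#' Draws `depth` tag copies: an artifact fraction as uniform random
#' 21-mers (CATG + random 17), the rest multinomially over the 3'-most
#' sense-strand virtual tags of observable genes with the stage's truth
#' proportions (genes without an indexable sense-strand site are
#' silently unobservable and their proportion mass is renormalised
#' away). Copies then receive single-base substitution errors in the
#' variable region with per-base rate `error_rate`, and N replacements
#' with per-copy rate `n_rate`. The returned total equals `depth`
#' exactly.
#'
#' @param truth A `simulation_truth`.
#' @param index The `virtual_tag_index` of the simulated transcriptome.
#' @param stage Stage number (column of the truth).
#' @param depth Library depth in tag copies (>= 0).
#' @param error_rate Per-base substitution rate in the 17-base variable
#'   region.
#' @param n_rate Per-copy N-replacement rate.
#' @param artifact_rate Fraction of copies that are random artifact tags.
#' @param seed Integer seed.
#' @param library_id Library identifier (default `"L<stage>"`).
#' @return A [raw_tag_set()].
#' @export
simulate_tag_library <- function(truth, index, stage, depth = 4.75e6,
                                 error_rate = 0.002, n_rate = 0.001,
                                 artifact_rate = 0.01, seed = 1L,
                                 library_id = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(index, "virtual_tag_index"))
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  depth <- as.integer(round(depth))
  library_id <- library_id %||% paste0("L", stage)
  if (depth == 0) return(raw_tag_set(numeric(0), library_id))

  sense1 <- index$tags[index$tags$strand == "sense" &
                         index$tags$site_rank == 1L, ]
  obs <- match(sense1$gene_id, truth$genes$gene_id)
  if (anyNA(obs)) stop("index genes missing from truth", call. = FALSE)
  props <- truth$stage_props[obs, stage]
  if (!length(props) || sum(props) <= 0) {
    stop("no observable expressed genes", call. = FALSE)
  }
  props <- props / sum(props)

  set.seed(seed)
  n_art <- rbinom(1L, depth, artifact_rate)
  n_main <- depth - n_art
  counts <- as.vector(rmultinom(1L, n_main, props))
  tags <- sense1$tag_seq

  # substitution errors: per-copy probability of >= 1 error over the
  # 17 variable bases; multi-error copies are approximated as single-base
  # errors (second-order at these rates)
  p_err <- 1 - (1 - error_rate)^17
  n_err <- rbinom(length(counts), counts, p_err)
  counts <- counts - n_err
  err_seq <- character(0)
  if (sum(n_err) > 0) {
    src <- rep.int(tags, n_err)
    pos <- sample(VARIABLE_START:TAG_LENGTH, length(src), replace = TRUE)
    alt <- sample.int(3L, length(src), replace = TRUE)
    err_seq <- substitute_base(src, pos, alt)
  }

  # N injection on the remaining intact copies
  n_n <- rbinom(length(counts), counts, n_rate)
  counts <- counts - n_n
  n_seq <- character(0)
  if (sum(n_n) > 0) {
    src <- rep.int(tags, n_n)
    pos <- sample(VARIABLE_START:TAG_LENGTH, length(src), replace = TRUE)
    for (p in unique(pos)) {
      i <- pos == p
      substr(src[i], p, p) <- "N"
    }
    n_seq <- src
  }

  art_seq <- character(0)
  if (n_art > 0) {
    m <- matrix(sample(DNA_BASES, 17L * n_art, replace = TRUE), nrow = n_art)
    art_seq <- paste0(TAG_ANCHOR, do.call(paste0, as.data.frame(m)))
  }

  all_seq <- c(rep.int(tags, counts), err_seq, n_seq, art_seq)
  raw_tag_set(aggregate_tag_counts(all_seq, rep(1, length(all_seq))),
              library_id)
}

#' Simulate a complete multi-stage study
#'
#' Convenience wrapper chaining [simulate_transcriptome()],
#' [build_virtual_tag_index()], [simulate_expression()] and one
#' [simulate_tag_library()] per stage, with per-stage seeds derived from
#' `seed`.
#'
#' @param n_genes Number of reference genes.
#' @param n_stages Number of stages/libraries.
#' @param depth Tag copies per library.
#' @param length_range Transcript length range.
#' @param de_fraction,fold_levels,sdlog Passed to
#'   [simulate_expression()].
#' @param error_rate,n_rate,artifact_rate Passed to
#'   [simulate_tag_library()].
#' @param seed Master seed; stage library seeds are `seed + 1000 * stage`.
#' @return List with `transcripts`, `index`, `truth`, `libraries`
#'   (named list of [raw_tag_set()]).
#' @export
simulate_study <- function(n_genes = 49053L, n_stages = 4L,
                           depth = 4.75e6, length_range = c(250L, 580L),
                           de_fraction = 0.15, fold_levels = c(2, 4, 8),
                           sdlog = 1.5, error_rate = 0.002, n_rate = 0.001,
                           artifact_rate = 0.01, seed = 1L) {
  transcripts <- simulate_transcriptome(n_genes, length_range, seed = seed)
  index <- build_virtual_tag_index(transcripts)
  truth <- simulate_expression(transcripts$gene_id, de_fraction,
                               fold_levels, sdlog, n_stages,
                               seed = seed + 1L)
  libraries <- lapply(seq_len(n_stages), function(s) {
    simulate_tag_library(truth, index, s, depth, error_rate, n_rate,
                         artifact_rate, seed = seed + 1000L * s)
  })
  names(libraries) <- paste0("L", seq_len(n_stages))
  list(transcripts = transcripts, index = index, truth = truth,
       libraries = libraries)
}

#' Write a raw tag library as FASTQ
#'
#' Emits one four-line record per tag copy (constant quality line; an
#' optional adaptor suffix follows the tag to exercise adaptor
#' trimming). Intended for small I/O round-trip fixtures.
#'
#' @param raw A [raw_tag_set()].
#' @param path Output FASTQ path.
#' @param adaptor Adaptor suffix appended to each read ("" for none).
#' @return `path`, invisibly.
#' @export
write_tag_fastq <- function(raw, path, adaptor = "") {
  stopifnot(inherits(raw, "raw_tag_set"))
  seqs <- rep.int(names(raw$counts), raw$counts)
  reads <- paste0(seqs, adaptor)
  qual <- vapply(nchar(reads), function(w) strrep("I", w), character(1))
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)),
                           reads, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation truth as JSON
#' @param truth A `simulation_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(list(
    seed = truth$seed,
    params = truth$params,
    genes = truth$genes,
    stage_props = as.data.frame(truth$stage_props)
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
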