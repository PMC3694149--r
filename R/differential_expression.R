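# Pairwise differential expression on tag counts.
#
# Test statistic: the exact conditional tag-count test. Given the two
# library sizes n_a, n_b and the observed counts (x, y), the conditional
# law of y given the total t = x + y is Binomial(t, n_b / (n_a + n_b))
# under the null of equal per-tag sampling rates. The two-sided p-value
# sums the probabilities of all outcomes no more probable than the
# observed one, which makes the test exactly symmetric under swapping the
# two libraries. Multiple testing is controlled with Benjamini-Hochberg
# step-up FDR. A gene is called differential at FDR <= 0.001 and
# |log2 ratio| >= 1 (defaults), with log2 ratios formed on TPM after
# flooring undetected sides at 0.01.

#' Exact conditional p-value for a pair of tag counts
#'
#' @param count_a,count_b Observed tag copies in the two libraries
#'   (vectors are recycled to common length).
#' @param n_a,n_b Clean tag totals of the two libraries.
#' @return Two-sided p-values in `[0, 1]`; symmetric under swapping the
#'   libraries: `tag_count_pvalue(x, n1, y, n2) ==
#'   tag_count_pvalue(y, n2, x, n1)`.
#' @examples
#' tag_count_pvalue(5, 1e6, 5, 1e6)   # most probable outcome: p = 1
#' tag_count_pvalue(0, 1e4, 20, 1e4)
#' @export
tag_count_pvalue <- function(count_a, n_a, count_b, n_b) {
  if (any(count_a < 0) || any(count_b < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(n_a <= 0) || any(n_b <= 0)) {
    stop("library totals must be > 0", call. = FALSE)
  }
  m <- max(length(count_a), length(count_b), length(n_a), length(n_b))
  count_a <- rep_len(count_a, m); count_b <- rep_len(count_b, m)
  n_a <- rep_len(n_a, m); n_b <- rep_len(n_b, m)
  vapply(seq_len(m), function(i) {
    conditional_binom_pvalue(count_a[i], n_a[i], count_b[i], n_b[i])
  }, numeric(1))
}

# Scalar core. The 1 + 1e-7 relative tolerance guards against floating
# point representation of tied outcome probabilities.
conditional_binom_pvalue <- function(x, n_a, y, n_b) {
  t <- x + y
  if (t == 0) return(1)
  pb <- n_b / (n_a + n_b)
  d <- dbinom(0:t, t, pb)
  obs <- d[y + 1L]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values (monotone in BH rank, capped at 1);
#'   empty input yields empty output.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes for one library pair
#'
#' Tests every gene detected in at least one of the two libraries.
#' `pair[1]` is the earlier developmental stage, `pair[2]` the later one;
#' "up" means higher in the later stage (positive log2 ratio).
#'
#' @param expr An `expression_table`.
#' @param pair Character vector of two distinct library ids,
#'   earlier stage first.
#' @param fdr_cutoff Significance threshold on FDR (default 0.001).
#' @param min_abs_log2 Threshold on |log2 ratio| (default 1).
#' @param tpm_floor Floor applied to undetected sides when forming
#'   ratios (default 0.01); stored TPM values are never floored.
#' @return List with `records` (data frame: `gene_id`, `count_a`,
#'   `count_b`, `tpm_a`, `tpm_b`, `log2_ratio`, `p_value`, `fdr`,
#'   `direction`, `significant`) and `summary`
#'   (`pair`, `total`, `up`, `down`).
#' @export
call_degs <- function(expr, pair, fdr_cutoff = 0.001, min_abs_log2 = 1,
                      tpm_floor = 0.01) {
  stopifnot(inherits(expr, "expression_table"))
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("pair must name two distinct libraries", call. = FALSE)
  }
  if (!all(pair %in% expr$libraries)) {
    stop("unknown library in pair: ",
         paste(setdiff(pair, expr$libraries), collapse = ", "),
         call. = FALSE)
  }
  if (fdr_cutoff <= 0 || min_abs_log2 < 0 || tpm_floor <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  a <- pair[1]; b <- pair[2]
  ca <- expr$counts[, a]; cb <- expr$counts[, b]
  keep <- which(ca + cb > 0)
  ca <- ca[keep]; cb <- cb[keep]
  ta <- expr$tpm[keep, a]; tb <- expr$tpm[keep, b]
  n_a <- expr$clean_totals[[a]]; n_b <- expr$clean_totals[[b]]

  # memoise on unique count pairs: tag libraries share many small counts
  key <- paste(ca, cb)
  uniq <- !duplicated(key)
  pv_u <- tag_count_pvalue(ca[uniq], n_a, cb[uniq], n_b)
  p <- pv_u[match(key, key[uniq])]
  fdr <- bh_fdr(p)
  lr <- log2(pmax(tb, tpm_floor) / pmax(ta, tpm_floor))
  sig <- fdr <= fdr_cutoff & abs(lr) >= min_abs_log2
  direction <- rep("none", length(sig))
  direction[sig & lr > 0] <- "up"
  direction[sig & lr < 0] <- "down"
  records <- data.frame(
    gene_id = expr$genes[keep],
    count_a = ca, count_b = cb,
    tpm_a = ta, tpm_b = tb,
    log2_ratio = lr, p_value = p, fdr = fdr,
    direction = direction, significant = sig,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(records = records,
       summary = list(pair = paste(a, b, sep = ":"),
                      total = sum(sig),
                      up = sum(direction == "up"),
                      down = sum(direction == "down")))
}

# Library pair ordering used in reports: for the canonical four-stage
# design the columns run L1:L2, L1:L3, L2:L3, L3:L4, L1:L4, L2:L4;
# otherwise all pairs in combination order.
library_pairs <- function(libs) {
  n <- length(libs)
  if (n < 2) return(list())
  cmb <- utils::combn(n, 2, simplify = FALSE)
  if (n == 4) {
    ordering <- list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(1, 4), c(2, 4))
    cmb <- ordering
  }
  lapply(cmb, function(ij) libs[ij])
}

#' Call DEGs for every library pair
#'
#' @inheritParams call_degs
#' @return List with `pairs` (list of [call_degs()] results, keyed by
#'   "A:B") and `summary` (data frame with one row per pair: `pair`,
#'   `total`, `up`, `down`).
#' @export
deg_all_pairs <- function(expr, fdr_cutoff = 0.001, min_abs_log2 = 1,
                          tpm_floor = 0.01) {
  prs <- library_pairs(expr$libraries)
  if (!length(prs)) stop("need at least two libraries", call. = FALSE)
  res <- lapply(prs, function(p) {
    call_degs(expr, p, fdr_cutoff, min_abs_log2, tpm_floor)
  })
  names(res) <- vapply(res, function(r) r$summary$pair, character(1))
  summary <- do.call(rbind, lapply(res, function(r) {
    data.frame(pair = r$summary$pair, total = r$summary$total,
               up = r$summary$up, down = r$summary$down,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(pairs = res, summary = summary)
}
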