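# Independent oracles and fixture builders used across the suite.
# Every oracle here is deliberately implemented with a different
# algorithm (character loops, lgamma enumeration, automaton DP) than the
# package code path it checks.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

random_transcripts <- function(n, max_len = 500, min_len = 30) {
  data.frame(
    gene_id = sprintf("t%03d", seq_len(n)),
    sequence = vapply(sample(min_len:max_len, n, replace = TRUE),
                      random_seq, character(1)),
    stringsAsFactors = FALSE
  )
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Positional-scan virtual tag oracle: walk every start position of both
# strand sequences by hand, no regex, and collect anchor+17 tags with
# their 3'-most-first ranks.
scan_tags_oracle <- function(transcripts) {
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    for (strand in c("sense", "antisense")) {
      s <- transcripts$sequence[i]
      if (strand == "antisense") s <- revcomp_chr(s)
      chars <- strsplit(s, "")[[1]]
      starts <- integer(0)
      for (p in seq_len(max(0, length(chars) - 3))) {
        if (chars[p] == "C" && chars[p + 1] == "A" &&
            chars[p + 2] == "T" && chars[p + 3] == "G" &&
            p + 20 <= length(chars)) {
          starts <- c(starts, p)
        }
      }
      if (!length(starts)) next
      starts <- rev(starts)  # 3'-most first
      for (r in seq_along(starts)) {
        tag <- substr(s, starts[r], starts[r] + 20)
        if (grepl("N", tag, fixed = TRUE)) next
        out[[length(out) + 1]] <- data.frame(
          tag_seq = tag, gene_id = transcripts$gene_id[i],
          strand = strand, site_rank = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag_seq = character(0), gene_id = character(0),
                      strand = character(0), site_rank = integer(0)))
  }
  do.call(rbind, out)
}

# Brute-force full-Hamming mapping oracle over every (tag, virtual tag)
# pair. Exact hits take precedence; the distinct gene set at the minimal
# distance (<= 1) decides the verdict.
hamming_map_oracle <- function(tags, vtag_seq, vtag_gene) {
  vm <- do.call(rbind, strsplit(vtag_seq, ""))
  n <- length(tags)
  status <- character(n)
  gene <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    qc <- strsplit(tags[i], "")[[1]]
    d <- rowSums(vm != matrix(qc, nrow(vm), length(qc), byrow = TRUE))
    dmin <- min(d)
    if (dmin > 1) {
      status[i] <- "unknown"
      next
    }
    gset <- unique(vtag_gene[d == dmin])
    mm[i] <- as.integer(dmin)
    if (length(gset) == 1) {
      status[i] <- "unambiguous"
      gene[i] <- gset
    } else {
      status[i] <- "ambiguous"
    }
  }
  data.frame(tag_seq = tags, status = status, gene_id = gene,
             mismatches = mm, stringsAsFactors = FALSE)
}

# Enumeration oracle for the conditional tag-count test, written with
# explicit log-factorials: P(k | t) = C(t, k) pb^k (1-pb)^(t-k),
# two-sided by summing outcomes no more probable than the observed one.
pvalue_enum_oracle <- function(x, n_a, y, n_b) {
  t <- x + y
  if (t == 0) return(1)
  pb <- n_b / (n_a + n_b)
  k <- 0:t
  logp <- lgamma(t + 1) - lgamma(k + 1) - lgamma(t - k + 1) +
    k * log(pb) + (t - k) * log1p(-pb)
  obs <- logp[y + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

# Exact probability that an iid-uniform DNA sequence of length L
# contains CATG, by automaton DP (CATG has no self-overlap; a failed
# extension restarts at 1 when the breaking character is C, else 0).
catg_contain_prob <- function(L) {
  pref <- c("C", "A", "T", "G")
  p <- c(1, 0, 0, 0, 0)
  for (i in seq_len(L)) {
    q <- c(0, 0, 0, 0, p[5])
    for (s in 0:3) {
      for (ch in BASES) {
        ns <- if (ch == pref[s + 1]) s + 1 else if (ch == "C") 1 else 0
        q[ns + 1] <- q[ns + 1] + p[s + 1] / 4
      }
    }
    p <- q
  }
  p[5]
}

# Small ready-made reference with known tags, shared by several tests.
toy_reference <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    sequence = c(
      # one sense site with exactly 17 downstream bases
      paste0("GG", "CATG", strrep("A", 17)),
      # one sense site, different variable region
      paste0("T", "CATG", "GTACGTACGTACGTACG", "TT"),
      # shares gA's tag exactly (ambiguity fixture)
      paste0("CATG", strrep("A", 17), "CC")
    ),
    stringsAsFactors = FALSE
  )
}

toy_clean <- function(counts, library_id = "lib") {
  clean_tags(raw_tag_set(counts, library_id))
}
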