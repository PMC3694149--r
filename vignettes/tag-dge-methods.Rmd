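---
title: "Methods: restriction-site-anchored tag profiling with tagdge"
author: "tagdge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction-site-anchored tag profiling with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

# The measurement model

`tagdge` analyses digital gene expression (DGE) libraries produced by
the *NlaIII*/*MmeI* tag chemistry. *NlaIII* cuts cDNA at its `CATG`
recognition site; an adapter ligated at the 3′-most site carries an
*MmeI* recognition sequence, and *MmeI* cuts 17 bp downstream, releasing
a tag of 4 anchor bases (`CATG`) plus 17 variable bases. Each transcript
is thus represented by (ideally) the 21-mer starting at its 3′-most
`CATG` site, and expression becomes a tag-counting problem: a library is
a multiset of 21-mers, and a gene's abundance is the copy count of its
tag(s).

Three features of this chemistry shape the whole pipeline:

* the anchor is chemically fixed — every genuine tag starts `CATG`, so
  sequencing errors worth modelling live in the 17 variable bases;
* a gene without a `CATG` site followed by at least 17 bases is
  invisible to the assay, so the fraction of reference genes carrying an
  indexable site bounds attainable detection;
* tag counts are closed (library size is fixed by sequencing depth), so
  between-library comparisons must condition on library sizes.

# Virtual tag reference

`build_virtual_tag_index()` enumerates every `CATG` occurrence with a
full 17-base downstream run, on the sense strand and on the reverse
complement of each transcript, and records `(tag_seq, gene_id, strand,
site_rank)` with `site_rank = 1` for the 3′-most eligible site of its
strand. All sites are indexed — not only the 3′-most — because partial
digestion and internal priming make non-3′-most tags observable in real
libraries; quantification policies that want the strict chemistry can
filter on `site_rank == 1`. Overlapping occurrences are enumerated
independently (each is a genuine recognition site), occurrences with
fewer than 17 downstream bases emit nothing (the chemistry cannot
produce a shorter tag), and tags containing `N` are suppressed as
unmatchable. Site ranks are assigned among full-length sites before the
`N` filter, so a suppressed tag leaves a visible gap in the ranking.

A useful structural fact: `CATG` is its own reverse complement, so sense
and antisense enumeration see the same genomic site positions and differ
only in which side of the site must carry the 17-base run. Counting
"genes with a CATG site" on either strand is therefore close to, but not
identical with, the sense-only count; `n_catg_genes` counts genes
contributing at least one tag on either strand, matching what the index
actually contains.

# Clean-tag filtering

`clean_tags()` applies the standard raw-to-clean cascade in a fixed
order — malformed length, then `N` content, then single-copy removal —
and writes a removal ledger attributing every removed copy to exactly
one reason, so `total_raw == total_clean + sum(ledger)` always holds
(this identity is property-tested on randomised inputs). The order
matters only for attribution, not for the surviving set; fixing it makes
ledgers deterministic. "Too short or too long" is interpreted as "not
exactly 21 bases after anchoring": no published numeric bounds exist for
the protocol, and the chemistry fixes the length, so length equality is
the only defensible reading. Input tag tables supplied as bare 17-mers
(a dialect some processed DGE datasets use) are anchored with `CATG` on
read-in.

Copy-number classification (`copy_distribution()`) uses the bins
2–5, 6–10, 11–20, 21–50, 51–100, >100 by default — the ranges
conventionally quoted for such libraries — and reports per-bin fractions
of distinct tags and of total copies; both must sum to one.

# Tag-to-gene mapping

`map_tags()` allows at most one mismatch, confined to the variable
region, implemented exactly as a hash lookup of the 3 × 17 = 51-sequence
substitution neighborhood. Exact matches take precedence: if a tag
matches any gene with zero mismatches, its 1-mismatch neighborhood is
ignored, preventing a sequencing-error neighborhood from overriding a
true hit. The verdict depends on the set of *distinct genes* at the
chosen mismatch level: one gene → `unambiguous`, several → `ambiguous`
(excluded from gene-level counting, the standard multi-gene filter),
none → `unknown`. Multiple sites or strands of the same gene never
create ambiguity. The implementation is validated against a brute-force
full-Hamming-distance oracle on randomised instances (the two agree
exactly because clean tags always carry the anchor, so anchor positions
can never contribute a mismatch).

Library summaries mirror the two-tier categorisation table of tag
studies: the "all mapped" tier counts unambiguous plus ambiguous tags,
the "unambiguous" tier only the former, each as copies and distinct
tags with percentages of the clean totals, plus gene counts as
percentages of the reference universe. All percentages are
`round(100 * num / den, 2)`.

# Quantification

Expression is reported in TPM in the tag-profiling sense — *tag copies
per million clean tags*: `tpm = copies * 1e6 / total_clean`. The
denominator is the clean total, not the mapped total, following the
unit's definition; no transcript-length normalisation applies because
the chemistry yields one tag per transcript end. The unfloored TPM
column therefore sums to `1e6 × (mapped copies / clean copies)`, an
identity the tests check directly. The floor value 0.01 TPM is applied
*only* when forming ratios for genes undetected on one side — a raw
count cannot produce 0.01 TPM in a multi-million-tag library, so the
floor is a ratio convention, not a stored value.

# Differential expression

The pairwise test is the exact conditional tag-count test: under the
null hypothesis that a gene is sampled at the same per-tag rate in both
libraries, the count in library B given the pair total `t = x + y` is
`Binomial(t, n_b / (n_a + n_b))`. The two-sided p-value sums the
probabilities of all outcomes no more probable than the observed one.
This formulation was chosen over the historical Bayesian tag-count
posterior because it is exactly symmetric under swapping the two
libraries (the posterior form is not when library sizes differ), while
agreeing with it closely at these depths; symmetry is part of the
function's contract and is property-tested. The implementation is
checked against an independent log-gamma enumeration oracle to 1e-9
over a grid of counts and library sizes.

Multiple testing uses Benjamini–Hochberg step-up FDR (`stats::p.adjust`;
a hand-executed BH oracle is frozen in the tests). A gene is called
differential when `FDR <= 0.001` and `|log2 ratio| >= 1` jointly — both
thresholds are configurable — with "up" meaning higher in the later
developmental stage of the pair. Genes undetected in both libraries are
not tested. For four-stage runs the report orders pairs
`L1:L2, L1:L3, L2:L3, L3:L4, L1:L4, L2:L4`, the conventional layout of
such studies.

# Saturation analysis

`saturation_curve()` asks how detected-gene count grows with sequencing
depth. Rather than drawing an independent without-replacement subsample
at every grid depth (which makes the curve non-monotone in general —
independent draws can lose genes as depth grows), the implementation
draws one seeded random permutation of all clean tag copies and counts,
at depth `d`, the genes whose first unambiguously assigned copy occurs
within the first `d` copies. Each depth is marginally an exact
without-replacement subsample, the curve is monotone by construction,
and the final grid point reproduces full-depth detection with no
sampling noise. The default grid is 20 evenly spaced depths ending at
full depth; detection means at least one unambiguous copy.

# The synthetic-data generator

The generator emulates the regime of a four-stage storage-organ study:
49053 reference genes, four libraries of ~4.75 million tags (the studies
this pipeline targets sequence 4.5–5.0 million), roughly 80% of genes
carrying an indexable `CATG` site, a heavy-tailed copy-number law with
the 2–5-copy bin dominating distinct clean tags (~40%), and a subset of
genes with planted stage-wise fold changes.

Defaults and why:

* `length_range = c(250, 580)` — short de-novo-assembled unigene
  fragments. With iid-uniform bases, the probability that a transcript
  of length L contains `CATG` is approximately `1 - (255/256)^(L-3)`
  (verified in the tests against an exact automaton DP); this range
  puts the either-strand indexable-gene fraction at ~79%.
* `sdlog = 1.5` — log-normal baseline proportions. Together with
  `error_rate = 0.002` this reproduces the target copy distribution at
  4.75 M depth (2–5-copy distinct fraction ≈ 0.39, 21–50 fraction
  ≈ 0.15). Both values were calibrated once against those regime
  targets and then frozen.
* `error_rate = 0.002` per variable-region base; erroneous copies are
  reallocated to single-substitution variants (multi-error copies are
  second-order at this rate and are ignored). Errors never touch the
  anchor, matching the mapping model: an anchor-damaged molecule would
  fail tag extraction altogether rather than map.
* `n_rate = 0.001` per copy — occasional `N` base calls, exercising the
  `contains_N` filter.
* `artifact_rate = 0.01` — random 21-mers exercising the unknown-tag
  path; being essentially unique, they are removed as singletons by
  cleaning, so simulated unknown fractions stay small.
* `de_fraction = 0.15`, `fold_levels = c(2, 4, 8)` — planted changes as
  step functions: a uniformly chosen onset stage from which the gene's
  proportion is multiplied or divided by the fold, then renormalised
  per stage. The 10–20% differential fraction matches what four-stage
  comparisons of this kind report.

Only the 3′-most sense tag is emitted per gene (the chemistry's dominant
product); genes without one are silently unobservable, mirroring the
~20% of real reference genes without a `CATG` site. Library totals are
exact: errors, `N`s and artifacts reallocate copies, never add them.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: transcript biology (UTRs, isoforms, GC bias),
quality-score structure beyond `N` placement, adaptor read-through and
chimeras, partial-digestion tags from non-3′-most sites (available as
indexed targets but never emitted), and an incomplete reference. The
last point matters most: real libraries map 55–65% of distinct tags and
leave ~20% of copies unknown because the reference is incomplete,
whereas the synthetic reference is complete by construction and noiseless
simulations map essentially everything. Mapping-rate figures from the
simulation are therefore not comparable to published ones; the
simulation validates the machinery (conservation, verdicts, recovery,
calibration), not the biology.

# Validation design

The test-suite acceptance layer recomputes, at fixed seeds:

* the two-decimal reporting arithmetic of the published categorisation
  and DEG tables from their printed integer inputs (bit-exact);
* mapping verdicts against the brute-force Hamming oracle on 100
  random instances (up to 200 tags × 500 virtual tags);
* exact-test p-values against the enumeration oracle on the grid
  `x, y ≤ 30`, `n ∈ {10³, 10⁴}`, to 1e-9, plus randomized swap symmetry;
* null control — twenty pairs of identical-proportion libraries
  (2000 genes, 500 k tags each) must yield at most 0.5% significant
  calls at the default thresholds;
* recovery — planted eight-fold genes with baseline TPM ≥ 50 at 4 M
  depth must be recovered with sensitivity ≥ 0.9 (denominator: planted
  genes that are observable, i.e. carry a sense-strand tag — an
  unobservable gene cannot be recovered by any method);
* conservation identities (cleaning ledger, verdict partition, TPM
  mass, distribution normalisation, saturation monotonicity);
* noiseless end-to-end closure: simulate → clean → map → quantify must
  recover at least 98.5% of observable gene counts within 3σ of their
  multinomial expectation (the binomial 3σ band itself covers ~99.7%;
  the margin absorbs singleton-filter truncation of shallow genes).

Problem sizes (2000–49053 genes, 0.3–4.75 M tags) are the package's
choice of desk-scale study conditions: large enough that the asymptotic
identities bind, small enough to re-run routinely.

# Numerical and degenerate-input choices

* Percentages use `round(..., 2)` (R's round-half-even at the third
  decimal, which matches the published tables at every checked value).
* The two-sided tail sum uses a `1 + 1e-7` relative tolerance when
  comparing outcome probabilities, guarding against floating-point
  representation of tied outcomes.
* Empty inputs: an empty reference builds an empty index with zero
  counts (but its CATG percentage is an error, not `NaN`); an empty read
  stream yields an empty raw set; an empty p-value vector yields an
  empty FDR vector; a zero-depth simulation yields an empty library.
  Zero clean totals make summaries and TPM errors — the quantities are
  undefined.
* Copy bins must partition `[2, ∞)` exactly; gaps, overlaps or a finite
  last bin are configuration errors.
* `sample()`-style index draws are made through `sample.int` on index
  vectors throughout the generator, so degenerate parameter sets (one
  fold level, equal length bounds) do not trigger R's scalar-`sample`
  expansion.

# Known limitations

* The mismatch budget is 0 or 1; indel-tolerant matching and
  mapping-quality scores are out of scope.
* The exact conditional test models sampling noise only; it has no
  between-replicate dispersion term (the target protocol has no
  replicates). Modern replicate designs should use a count model with
  dispersion instead.
* Detection definitions differ across published summaries of such
  studies (mapped-gene counts vs "transcripts identified"); the package
  exposes a detection threshold (`min_count`) rather than guessing
  which definition produced which published number.
* Saturation counts genes detected by unambiguous tags only; ambiguous
  rescue strategies are not implemented.
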