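Package: tagdge
Title: Restriction-Site-Anchored Digital Gene Expression Tag Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tag-based digital gene expression (DGE/SAGE-style)
    profiling of transcript libraries: construction of a virtual
    CATG-anchored 21-base tag reference from transcript sequences,
    raw-tag filtering into clean tags with a copy-conservation removal
    ledger, tag-to-gene mapping with at most one mismatch in the variable
    region, per-million-clean-tag (TPM) quantification, exact-test
    differential expression calling with Benjamini-Hochberg FDR control,
    sequencing-saturation analysis, consolidated run reports, and a seeded
    synthetic-library generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
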