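Package: granusum
Title: Granularity Analysis for Extractive Summarization of Clinical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying which textual granularity (whole sentences,
    clinical segments, or clauses) works best for extractive summarization of
    free-text health records, such as generating hospital discharge summaries
    from daily inpatient notes. Provides ROUGE-N and union-LCS ROUGE-L metrics,
    greedy ROUGE-2 oracle label construction under a character budget, a family
    of sentence and sub-sentence splitters including a trainable pointer-network
    segmenter, a unit-level extractive classifier with self-attention, span
    relation statistics between competing segmentations, and a synthetic
    parallel-corpus generator that emulates the statistical shape of restricted
    clinical archives so that the full pipeline is testable without access to
    protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
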