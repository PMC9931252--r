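# Span relations between competing segmentations, and the copy-paste rate.
#
# Comparing a clinical-segment segmentation with a clause segmentation of
# the same sentence, any two intersecting units stand in one of four
# relations: Equal (identical spans), Inclusive (segment strictly contains
# clause), Included (clause strictly contains segment) or Overlap (they
# intersect without containment).  Disjoint pairs are excluded from the
# totals, matching the four-way reporting convention.

#' Classify the relation between a segment span and a clause span
#'
#' @param segment,clause Units: lists or one-row data.frames with fields
#'   `sentence_index`, `start`, `end` (half-open token intervals in the same
#'   sentence).
#' @return One of `"equal"`, `"inclusive"`, `"included"`, `"overlap"`,
#'   `"disjoint"`.
#' @export
classify_relation <- function(segment, clause) {
  if (segment$sentence_index != clause$sentence_index)
    stop("units belong to different sentences")
  classify_interval_relation(segment$start, segment$end,
                             clause$start, clause$end)
}

classify_interval_relation <- function(s1, e1, s2, e2) {
  stopifnot(s1 < e1, s2 < e2)
  if (s1 == s2 && e1 == e2) return("equal")
  if (min(e1, e2) <= max(s1, s2)) return("disjoint")
  if (s1 <= s2 && e2 <= e1) return("inclusive")
  if (s2 <= s1 && e1 <= e2) return("included")
  "overlap"
}

#' Four-way relation statistics between two segmentations of a corpus
#'
#' Counts every intersecting (segment, clause) pair within each sentence of
#' every source and summary document.  Disjoint pairs are not counted.
#'
#' @param corpus A `granusum_corpus`.
#' @param segment_boundaries,clause_boundaries Optional boundary overrides:
#'   lists with one element per document pair, each a list
#'   `list(source = <per-sentence boundary list>, summary = <...>)`.
#'   Defaults to the corpus' gold segment/clause boundaries.
#' @return A list of class `relation_counts`: `counts` and `proportions`,
#'   both named vectors over equal/inclusive/included/overlap, plus `total`.
#' @export
relation_statistics <- function(corpus, segment_boundaries = NULL,
                                clause_boundaries = NULL) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  counts <- c(equal = 0, inclusive = 0, included = 0, overlap = 0)
  for (i in seq_along(corpus)) {
    p <- corpus[[i]]
    for (side in c("source", "summary")) {
      doc <- p[[side]]
      for (j in seq_along(doc$sentences)) {
        sent <- doc$sentences[[j]]
        n <- nrow(sent$tokens)
        sb <- segment_boundaries[[i]][[side]][[j]] %||% sent$seg_bounds
        cb <- clause_boundaries[[i]][[side]][[j]] %||% sent$clause_bounds
        seg_s <- c(0L, sb); seg_e <- c(sb, n)
        cl_s <- c(0L, cb); cl_e <- c(cb, n)
        for (a in seq_along(seg_s)) {
          hit <- cl_s < seg_e[a] & cl_e > seg_s[a]
          for (b in which(hit)) {
            rel <- classify_interval_relation(seg_s[a], seg_e[a],
                                              cl_s[b], cl_e[b])
            counts[rel] <- counts[rel] + 1
          }
        }
      }
    }
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 proportions = if (total > 0) counts / total else counts,
                 total = total),
            class = "relation_counts")
}

#' @export
print.relation_counts <- function(x, ...) {
  cat("<relation_counts>\n")
  df <- data.frame(count = x$counts, pct = sprintf("%.1f%%",
                                                   100 * x$proportions))
  print(df)
  invisible(x)
}

#' Verbatim copy-paste rate of a summary
#'
#' Fraction of summary sentences (with at least `min_tokens` tokens) whose
#' entire token sequence occurs verbatim as a contiguous run in the source
#' document's token stream.  This is the preliminary statistic motivating
#' extractive summarization of clinical records: a fifth to a third of
#' discharge-summary sentences are copied from the inpatient record.
#'
#' @param pair A [document_pair()].
#' @param min_tokens Minimum summary sentence length considered (default 3).
#' @return A proportion in `[0, 1]`; 0 if no summary sentence qualifies.
#' @export
copy_paste_rate <- function(pair, min_tokens = 3L) {
  stopifnot(inherits(pair, "document_pair"), min_tokens >= 1L)
  src <- document_tokens(pair$source)
  hay <- paste0("\u241f", paste(src, collapse = "\u241f"), "\u241f")
  sents <- pair$summary$sentences
  lens <- vapply(sents, function(s) nrow(s$tokens), integer(1))
  keep <- which(lens >= min_tokens)
  if (!length(keep)) return(0)
  hits <- vapply(keep, function(i) {
    needle <- paste0("\u241f",
                     paste(sents[[i]]$tokens$surface, collapse = "\u241f"),
                     "\u241f")
    grepl(needle, hay, fixed = TRUE)
  }, logical(1))
  mean(hits)
}

#' Mean copy-paste rate over a corpus
#'
#' @param corpus A `granusum_corpus`.
#' @param min_tokens See [copy_paste_rate()].
#' @return Mean of per-document rates.
#' @export
corpus_copy_paste_rate <- function(corpus, min_tokens = 3L) {
  mean(vapply(corpus, copy_paste_rate, numeric(1), min_tokens = min_tokens))
}
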