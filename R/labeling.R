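# Oracle (pseudo) label construction.
#
# Extractive training labels are built without manual annotation: every unit
# of the source document is scored by ROUGE-2 F1 against the reference
# summary, units are sorted by score, and the top of the list is selected
# greedily until a character budget is exceeded.  Selected units get label 1.

# Fast per-unit ROUGE-2 F1 against a fixed reference: the reference bigram
# table is built once.  Equivalent to rouge_n(unit, reference, 2)$f1.
bigram_strings <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  paste(tokens[-length(tokens)], tokens[-1L], sep = "\u241f")
}

#' Score source units by ROUGE-2 F1 against the reference summary
#'
#' The reference side is the full summary token stream.  Units with fewer
#' than two tokens, or an empty reference, score 0.
#'
#' @param units Unit data.frame from [enumerate_units()] over the source
#'   document.
#' @param source The source [document()].
#' @param reference The reference summary [document()].
#' @return `units` with a `rouge2_f1` column appended.
#' @export
score_units <- function(units, source, reference) {
  ref_tokens <- document_tokens(reference)
  rc <- table(bigram_strings(ref_tokens))
  n_ref <- sum(rc)
  scores <- numeric(nrow(units))
  if (n_ref > 0L) {
    for (r in seq_len(nrow(units))) {
      toks <- unit_tokens(source$sentences[[units$sentence_index[r]]],
                          units$start[r], units$end[r])
      cb <- bigram_strings(toks)
      if (!length(cb)) next
      cc <- table(cb)
      shared <- intersect(names(cc), names(rc))
      m <- if (length(shared)) sum(pmin(cc[shared], rc[shared])) else 0
      if (m > 0) {
        rec <- m / n_ref
        prec <- m / sum(cc)
        scores[r] <- 2 * rec * prec / (rec + prec)
      }
    }
  }
  units$rouge2_f1 <- scores
  units
}

#' Assign binary oracle labels under a character budget
#'
#' Units are ranked by `rouge2_f1` descending (ties broken by document
#' order) and selected greedily.  Selection stops at the first unit whose
#' inclusion makes the cumulative character length exceed `budget_chars`;
#' by default that overflowing unit is still included ("include-then-stop").
#' Consequently the positive units' total length is at most the budget plus
#' one unit.
#'
#' @param scored_units Output of [score_units()].
#' @param budget_chars Positive character budget (default 1200, the average
#'   reference summary length the procedure emulates).
#' @param include_overflow If `FALSE`, the unit that overflows the budget is
#'   excluded instead of included.
#' @return `scored_units` with a binary `label` column appended, original
#'   document order preserved.
#' @export
assign_labels <- function(scored_units, budget_chars = 1200L,
                          include_overflow = TRUE) {
  stopifnot(budget_chars > 0, "rouge2_f1" %in% names(scored_units))
  scored_units$label <- as.integer(
    greedy_select(scored_units$rouge2_f1, scored_units$char_len,
                  budget_chars, include_overflow))
  scored_units
}

# Shared budgeted ranking rule: sort by score descending (ties by original
# order), take greedily; the first item whose inclusion pushes the cumulative
# character length over the budget is included (include_overflow) or dropped,
# then selection stops.  Returns a logical selection vector.
greedy_select <- function(scores, char_lens, budget_chars,
                          include_overflow = TRUE) {
  n <- length(scores)
  sel <- logical(n)
  if (n == 0L) return(sel)
  ord <- order(-scores, seq_len(n))
  cum <- cumsum(char_lens[ord])
  over <- which(cum > budget_chars)
  n_sel <- if (!length(over)) n
           else if (include_overflow) over[1L]
           else over[1L] - 1L
  sel[ord[seq_len(n_sel)]] <- TRUE
  sel
}

#' Oracle-label a whole corpus at one granularity
#'
#' Runs [enumerate_units()], [score_units()] and [assign_labels()] for every
#' document pair.
#'
#' @param corpus A `granusum_corpus`.
#' @param granularity `"sentence"`, `"segment"` or `"clause"`.
#' @param budget_chars Character budget passed to [assign_labels()].
#' @param boundaries Optional list (one element per document pair) of
#'   per-sentence boundary lists, e.g. predicted segment boundaries;
#'   defaults to the gold boundaries stored in the corpus.
#' @param include_overflow See [assign_labels()].
#' @return A list of class `labeled_corpus`: `docs` (one labeled unit
#'   data.frame per pair), `granularity`, `budget_chars`.
#' @export
oracle_label_corpus <- function(corpus, granularity, budget_chars = 1200L,
                                boundaries = NULL, include_overflow = TRUE) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  docs <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    p <- corpus[[i]]
    units <- enumerate_units(p$source, granularity,
                             boundaries = boundaries[[i]] %||% NULL)
    units <- score_units(units, p$source, p$summary)
    docs[[i]] <- assign_labels(units, budget_chars, include_overflow)
  }
  structure(list(docs = docs, granularity = granularity,
                 budget_chars = budget_chars,
                 doc_ids = vapply(corpus, function(p) p$source$doc_id,
                                  character(1))),
            class = "labeled_corpus")
}

#' Split a corpus into train/development/test sets
#'
#' Documents are drawn without replacement, deterministically for a given
#' seed; the remainder forms the training set.
#'
#' @param corpus A `granusum_corpus`.
#' @param n_dev,n_test Development and test set sizes
#'   (`n_dev + n_test < length(corpus)`).
#' @param seed Integer seed.
#' @return List with `train`, `dev`, `test` corpora.
#' @export
split_dataset <- function(corpus, n_dev, n_test, seed = 1L) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  n <- length(corpus)
  if (n_dev + n_test >= n)
    stop("not enough documents: need n_dev + n_test < ", n)
  set.seed(seed)
  held <- sample.int(n, n_dev + n_test)
  dev_idx <- held[seq_len(n_dev)]
  test_idx <- held[n_dev + seq_len(n_test)]
  train_idx <- setdiff(seq_len(n), held)
  list(train = as_corpus(unclass(corpus)[train_idx]),
       dev = as_corpus(unclass(corpus)[dev_idx]),
       test = as_corpus(unclass(corpus)[test_idx]))
}
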