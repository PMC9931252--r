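# ROUGE-N and union-LCS ROUGE-L.
#
# Token identity is exact surface match; no stemming or stopword removal.
# Degenerate inputs (empty sequences, 0/0 ratios) always yield a score of 0
# rather than an error, because noisy clinical text guarantees they occur.

rouge_score <- function(recall, precision) {
  f1 <- if ((recall + precision) > 0) 2 * recall * precision / (recall + precision) else 0
  structure(list(recall = recall, precision = precision, f1 = f1),
            class = "rouge_score")
}

#' @export
print.rouge_score <- function(x, ...) {
  cat(sprintf("<rouge_score> R=%.4f P=%.4f F1=%.4f\n",
              x$recall, x$precision, x$f1))
  invisible(x)
}

ngram_counts <- function(tokens, n) {
  len <- length(tokens)
  if (len < n) return(integer(0))
  if (n == 1L) {
    grams <- tokens
  } else {
    m <- len - n + 1L
    grams <- tokens[seq_len(m)]
    for (k in 2:n) grams <- paste(grams, tokens[k:(k + m - 1L)], sep = "\u241f")
  }
  table(grams)
}

#' ROUGE-N between a candidate and a reference token sequence
#'
#' N-gram co-occurrence with clipped (multiset) matching: each n-gram
#' contributes the minimum of its candidate and reference multiplicities.
#' Recall divides by the number of reference n-grams, precision by the number
#' of candidate n-grams, and F1 is their harmonic mean.
#'
#' @param candidate Character vector of candidate tokens.
#' @param reference Character vector of reference tokens.
#' @param n N-gram order (>= 1).
#' @return A `rouge_score` list with `recall`, `precision`, `f1`, all in
#'   `[0, 1]`.  A side shorter than `n` scores 0 on that side.
#' @export
rouge_n <- function(candidate, reference, n = 1L) {
  stopifnot(n >= 1L)
  rc <- ngram_counts(reference, n)
  cc <- ngram_counts(candidate, n)
  shared <- intersect(names(rc), names(cc))
  match_ct <- if (length(shared)) sum(pmin(rc[shared], cc[shared])) else 0
  recall <- if (sum(rc) > 0) match_ct / sum(rc) else 0
  precision <- if (sum(cc) > 0) match_ct / sum(cc) else 0
  rouge_score(recall, precision)
}

# Length table of longest common subsequences: d[i+1, j+1] = LCS(a[1..i], b[1..j])
lcs_table <- function(a, b) {
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    eq <- a[i] == b
    for (j in seq_len(n)) {
      d[i + 1L, j + 1L] <- if (eq[j]) d[i, j] + 1L else max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  d
}

# Reference positions of one LCS between reference r and candidate c, chosen
# leftmost-greedily in the reference: among all LCSs, the lexicographically
# smallest set of reference positions.  Uses a suffix LCS table: at (i, j)
# with `need` matches still required, skipping a candidate token is preferred
# whenever it keeps `need` achievable, which leaves the earliest reference
# positions available for matching.
lcs_positions <- function(r, c) {
  m <- length(r); n <- length(c)
  if (m == 0L || n == 0L) return(integer(0))
  suf <- matrix(0L, m + 2L, n + 2L)
  for (i in m:1) {
    eq <- r[i] == c
    for (j in n:1) {
      suf[i, j] <- if (eq[j]) suf[i + 1L, j + 1L] + 1L else max(suf[i + 1L, j], suf[i, j + 1L])
    }
  }
  need <- suf[1L, 1L]
  pos <- integer(0)
  i <- 1L; j <- 1L
  while (need > 0L && i <= m && j <= n) {
    if (r[i] == c[j] && suf[i + 1L, j + 1L] == need - 1L) {
      pos <- c(pos, i); i <- i + 1L; j <- j + 1L; need <- need - 1L
    } else if (suf[i, j + 1L] == need) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  pos
}

#' Union-LCS score of one reference sentence against candidate sentences
#'
#' For each candidate sentence, one longest common subsequence with the
#' reference is taken as a set of reference token positions (chosen
#' deterministically, leftmost in the reference); the score is the size of
#' the union of those position sets.  With reference
#' `(w1, w2, w3, w4)` and candidates `(w1, w2, w6, w7)` and
#' `(w1, w8, w4, w9)`, the union is `{w1, w2, w4}` and the score is 3.
#'
#' @param reference Character vector, the reference sentence tokens.
#' @param candidates List of character vectors, the candidate sentences.
#' @return Integer: number of distinct reference positions covered.  An empty
#'   candidate list scores 0.
#' @export
lcs_union <- function(reference, candidates) {
  stopifnot(length(reference) >= 1L)
  if (length(candidates) == 0L) return(0L)
  covered <- unique(unlist(lapply(candidates, function(c)
    lcs_positions(reference, c)), use.names = FALSE))
  length(covered)
}

#' Union-LCS ROUGE-L over sentence-split texts
#'
#' Recall sums [lcs_union()] over reference sentences and divides by the
#' total reference token count; precision divides the same numerator by the
#' total candidate token count; F1 is the harmonic mean.
#'
#' @param reference_sentences List of character vectors (>= 1 sentence).
#' @param candidate_sentences List of character vectors (may be empty).
#' @return A `rouge_score`.
#' @export
rouge_l <- function(reference_sentences, candidate_sentences) {
  stopifnot(length(reference_sentences) >= 1L)
  ref_tokens <- sum(lengths(reference_sentences))
  cand_tokens <- sum(lengths(candidate_sentences))
  if (cand_tokens == 0L || ref_tokens == 0L) return(rouge_score(0, 0))
  hits <- sum(vapply(reference_sentences, function(r) {
    if (length(r) == 0L) 0L else lcs_union(r, candidate_sentences)
  }, integer(1)))
  rouge_score(hits / ref_tokens, hits / cand_tokens)
}
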