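# Shared fixtures and independent oracle implementations.
#
# The oracles here deliberately use different algorithms and code paths from
# the package (character-by-character scanners, nested-loop counters,
# exhaustive enumeration) so that agreement is meaningful.

FS <- "\u3002"  # ideographic full stop

# quick sentence builder: surfaces from a space-separated string, POS tags
# recycled
mk_sent <- function(spec, pos = "noun", seg = integer(0), cl = integer(0)) {
  surf <- strsplit(spec, " ", fixed = TRUE)[[1]]
  sentence_record(surf, rep_len(pos, length(surf)), seg_bounds = seg,
                  clause_bounds = cl)
}

mk_pos_sent <- function(surfaces, pos, seg = integer(0), cl = integer(0)) {
  sentence_record(surfaces, pos, seg_bounds = seg, clause_bounds = cl)
}

# a tiny two-pair corpus used by I/O tests
tiny_corpus <- function() {
  s1 <- mk_sent("ab cd ef gh", seg = 2L, cl = c(1L, 2L))
  s2 <- mk_sent("xy z")
  sum1 <- mk_sent("ab cd")
  p1 <- document_pair(document("d1", list(s1, s2)),
                      document("d1-s", list(sum1)),
                      data.frame(summary_sent = 1L, summary_start = 0L,
                                 summary_end = 2L, source_sent = 1L,
                                 source_start = 0L, source_end = 2L))
  p2 <- document_pair(document("d2", list(mk_sent("q r s"))),
                      document("d2-s", list(mk_sent("q r"))))
  as_corpus(list(p1, p2))
}

# --- brute-force sentence splitter (rules: full stop ends a sentence and is
# kept; a line break ends the current sentence and is dropped) -------------
bf_split_sentences <- function(text, fullstops = FS) {
  out <- character(0)
  buf <- ""
  for (ch in strsplit(text, "")[[1]]) {
    if (ch == "\n") {
      if (nzchar(buf)) out <- c(out, buf)
      buf <- ""
    } else if (ch %in% fullstops) {
      out <- c(out, paste0(buf, ch))
      buf <- ""
    } else {
      buf <- paste0(buf, ch)
    }
  }
  if (nzchar(buf)) out <- c(out, buf)
  out
}

# random noisy text over a tiny alphabet with full stops and line breaks
random_noisy_text <- function(len) {
  paste0(sample(c("a", "b", "c", FS, "\n"), len, replace = TRUE,
                prob = c(0.3, 0.25, 0.2, 0.15, 0.1)), collapse = "")
}

# --- brute-force ROUGE-N: nested loops over n-gram occurrences ------------
bf_rouge_n <- function(cand, ref, n) {
  grams <- function(x) {
    if (length(x) < n) return(list())
    lapply(seq_len(length(x) - n + 1L), function(i) x[i:(i + n - 1L)])
  }
  gc <- grams(cand); gr <- grams(ref)
  used <- rep(FALSE, length(gc))
  m <- 0L
  for (g in gr) {
    for (j in seq_along(gc)) {
      if (!used[j] && identical(gc[[j]], g)) {
        used[j] <- TRUE
        m <- m + 1L
        break
      }
    }
  }
  recall <- if (length(gr)) m / length(gr) else 0
  precision <- if (length(gc)) m / length(gc) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1)
}

# --- exhaustive LCS machinery ---------------------------------------------
# all sets of reference positions realizing an LCS of r and c
bf_all_lcs_position_sets <- function(r, c) {
  L <- granusum:::lcs_table(r, c)[length(r) + 1L, length(c) + 1L]
  if (L == 0L) return(list(integer(0)))
  res <- list()
  rec <- function(i, j, picked) {
    need <- L - length(picked)
    if (need == 0L) {
      res[[length(res) + 1L]] <<- picked
      return()
    }
    if (i > length(r) || j > length(c)) return()
    # prune: remaining LCS must reach `need`
    for (ii in i:length(r)) {
      for (jj in j:length(c)) {
        if (r[ii] == c[jj]) {
          sub <- granusum:::lcs_table(
            if (ii < length(r)) r[(ii + 1L):length(r)] else character(0),
            if (jj < length(c)) c[(jj + 1L):length(c)] else character(0))
          if (1L + sub[nrow(sub), ncol(sub)] >= need)
            rec(ii + 1L, jj + 1L, c(picked, ii))
        }
      }
    }
  }
  rec(1L, 1L, integer(0))
  unique(res)
}

# lexicographically smallest LCS reference-position set (independent oracle
# for the deterministic leftmost choice)
bf_leftmost_lcs_positions <- function(r, c) {
  sets <- bf_all_lcs_position_sets(r, c)
  key <- vapply(sets, function(s) paste(sprintf("%04d", s), collapse = ","),
                character(1))
  sets[[order(key)[1L]]]
}

# maximum achievable union size over all per-candidate LCS choices
bf_max_lcs_union <- function(r, cands) {
  sets_per_cand <- lapply(cands, function(c) bf_all_lcs_position_sets(r, c))
  best <- 0L
  rec <- function(k, acc) {
    if (k > length(sets_per_cand)) {
      best <<- max(best, length(acc))
      return()
    }
    for (s in sets_per_cand[[k]]) rec(k + 1L, union(acc, s))
  }
  rec(1L, integer(0))
  best
}

# random token sequence over a small vocabulary
rand_tokens <- function(len, vocab = paste0("w", 1:6)) {
  sample(vocab, len, replace = TRUE)
}

# --- brute-force rule splitters -------------------------------------------
bf_split_fullstop <- function(pos) {
  out <- integer(0)
  for (k in seq_along(pos))
    if (pos[k] == "fullstop" && k < length(pos)) out <- c(out, k)
  out
}

bf_split_fullstop_verb <- function(pos) {
  out <- bf_split_fullstop(pos)
  for (k in seq_along(pos)) {
    if (pos[k] != "verb") next
    j <- k + 1L
    while (j <= length(pos) && pos[j] != "noun") j <- j + 1L
    if (j <= length(pos) && j - 1L >= 1L && j - 1L < length(pos))
      out <- c(out, j - 1L)
  }
  sort(unique(out))
}

random_pos_sentence <- function(len) {
  tags <- sample(c("noun", "noun_nonindependent", "verb", "particle",
                   "fullstop", "other"), len, replace = TRUE,
                 prob = c(0.3, 0.1, 0.2, 0.2, 0.1, 0.1))
  mk_pos_sent(paste0("t", seq_len(len)), tags)
}

# small deterministic desk corpus shared by slower tests
desk_corpus <- function(n_docs = 30, seed = 404, ...) {
  generate_corpus(generator_config(n_docs = n_docs, sentences_per_doc = 20,
                                   summary_sentences = 6,
                                   summary_char_budget = 200, seed = seed,
                                   ...))
}
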