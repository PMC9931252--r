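test_that("classify_relation covers the textbook cases", {
  u <- function(s, e) list(sentence_index = 1L, start = s, end = e)
  expect_identical(classify_relation(u(0, 4), u(0, 4)), "equal")
  expect_identical(classify_relation(u(0, 4), u(1, 3)), "inclusive")
  expect_identical(classify_relation(u(1, 3), u(0, 4)), "included")
  expect_identical(classify_relation(u(0, 3), u(2, 5)), "overlap")
  expect_identical(classify_relation(u(0, 2), u(2, 4)), "disjoint")
  expect_error(classify_relation(list(sentence_index = 1, start = 0, end = 2),
                                 list(sentence_index = 2, start = 0, end = 2)),
               "different sentences")
})

test_that("classify_relation equals the set-theoretic definition exhaustively", {
  for (n in 2:6) {
    spans <- list()
    for (s in 0:(n - 1)) for (e in (s + 1):n)
      spans[[length(spans) + 1L]] <- c(s, e)
    for (a in spans) for (b in spans) {
      set_a <- (a[1] + 1):a[2]
      set_b <- (b[1] + 1):b[2]
      inter <- intersect(set_a, set_b)
      expected <- if (setequal(set_a, set_b)) "equal"
        else if (!length(inter)) "disjoint"
        else if (all(set_b %in% set_a)) "inclusive"
        else if (all(set_a %in% set_b)) "included"
        else "overlap"
      got <- granusum:::classify_interval_relation(a[1], a[2], b[1], b[2])
      expect_identical(got, expected,
                       info = sprintf("[%d,%d) vs [%d,%d)", a[1], a[2],
                                      b[1], b[2]))
      # antisymmetry under swapping arguments
      swapped <- granusum:::classify_interval_relation(b[1], b[2], a[1], a[2])
      expect_identical(swapped, switch(got, inclusive = "included",
                                       included = "inclusive", got))
    }
  }
})

test_that("relation_statistics matches hand enumeration and excludes disjoint", {
  # 7-token sentence, segments {3}, clauses {2,5}:
  # [0,3)&[0,2) inclusive, [0,3)&[2,5) overlap,
  # [3,7)&[2,5) overlap,   [3,7)&[5,7) inclusive
  s <- mk_sent("a b c d e f g", seg = 3L, cl = c(2L, 5L))
  smr <- mk_sent("x")  # single unit both ways: one equal pair
  pair <- document_pair(document("d", list(s)), document("d-s", list(smr)))
  rs <- relation_statistics(as_corpus(list(pair)))
  expect_equal(unname(rs$counts["inclusive"]), 2)
  expect_equal(unname(rs$counts["overlap"]), 2)
  expect_equal(unname(rs$counts["equal"]), 1)  # from the summary sentence
  expect_equal(unname(rs$counts["included"]), 0)
  expect_equal(sum(rs$proportions), 1)
})

test_that("identical segmentations give 100% equal; refinement gives equal+inclusive", {
  corp <- desk_corpus(n_docs = 4, seed = 51)
  seg_as_clause <- lapply(corp, function(p) list(
    source = lapply(p$source$sentences, `[[`, "seg_bounds"),
    summary = lapply(p$summary$sentences, `[[`, "seg_bounds")))
  rs_same <- relation_statistics(corp, clause_boundaries = seg_as_clause)
  expect_equal(unname(rs_same$proportions["equal"]), 1)
  # generated clause boundaries refine segments: only equal + inclusive
  rs <- relation_statistics(corp)
  expect_equal(unname(rs$counts["included"]), 0)
  expect_equal(unname(rs$counts["overlap"]), 0)
  expect_gt(unname(rs$counts["inclusive"]), 0)
})

test_that("relation proportions sum to one and ignore processing order", {
  corp <- desk_corpus(n_docs = 5, seed = 52)
  rs1 <- relation_statistics(corp)
  rs2 <- relation_statistics(as_corpus(rev(unclass(corp))))
  expect_equal(rs1$counts, rs2$counts)
  expect_equal(sum(rs1$proportions), 1)
})

test_that("copy_paste_rate counts verbatim sentences only", {
  src <- document("s", list(mk_sent("a b c d e"), mk_sent("f g h")))
  # summary: one verbatim copy of a contiguous source run, one novel sentence
  smr <- document("s-s", list(mk_sent("b c d"), mk_sent("x y z")))
  pair <- document_pair(src, smr)
  expect_equal(copy_paste_rate(pair, min_tokens = 3), 0.5)
  # below min_tokens nothing qualifies
  smr2 <- document("s2", list(mk_sent("b c")))
  expect_equal(copy_paste_rate(document_pair(src, smr2), min_tokens = 3), 0)
  # disjoint vocabulary: zero
  smr3 <- document("s3", list(mk_sent("p q r")))
  expect_equal(copy_paste_rate(document_pair(src, smr3), min_tokens = 3), 0)
  # token-boundary safety: "ab" in source must not match summary "a b"
  src2 <- document("t", list(mk_sent("ab c d")))
  smr4 <- document("t-s", list(mk_sent("a b c")))
  expect_equal(copy_paste_rate(document_pair(src2, smr4), min_tokens = 3), 0)
})

test_that("corpus copy-paste rate tracks the planted verbatim fraction", {
  # noise off so planted copies stay verbatim; single-segment copy sentences
  # that span a whole source sentence are the planted verbatim truth
  cfg <- generator_config(n_docs = 200, sentences_per_doc = 15,
                          summary_sentences = 8, summary_char_budget = 400,
                          noise_fullstop_drop_prob = 0,
                          noise_linebreak_prob = 0, seed = 53)
  corp <- generate_corpus(cfg)
  truth <- vapply(corp, function(p) {
    sents <- p$summary$sentences
    lens <- vapply(sents, function(s) nrow(s$tokens), integer(1))
    eligible <- which(lens >= 3L)
    if (!length(eligible)) return(0)
    planted <- vapply(eligible, function(i) {
      if (is.null(p$provenance)) return(FALSE)
      pv <- p$provenance[p$provenance$summary_sent == i, , drop = FALSE]
      if (nrow(pv) != 1L) return(FALSE)
      # a single copied segment spanning the whole summary sentence except
      # its appended full stop, with the source copy immediately followed by
      # a full stop (sentence-final segment), reproduces the source run
      # token for token
      src_sent <- p$source$sentences[[pv$source_sent]]
      cover_summary <- pv$summary_start == 0L &&
        pv$summary_end == lens[i] - 1L
      smr_ends_fs <- sents[[i]]$tokens$pos[lens[i]] == "fullstop"
      followed_by_fs <- pv$source_end < nrow(src_sent$tokens) &&
        src_sent$tokens$pos[pv$source_end + 1L] == "fullstop"
      cover_summary && smr_ends_fs && followed_by_fs
    }, logical(1))
    mean(planted)
  }, numeric(1))
  est <- corpus_copy_paste_rate(corp, min_tokens = 3L)
  expect_lt(abs(est - mean(truth)), 0.03)
})
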