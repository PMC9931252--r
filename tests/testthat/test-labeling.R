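test_that("score_units matches rouge_n on each unit", {
  corp <- desk_corpus(n_docs = 2, seed = 41)
  p <- corp[[1]]
  units <- enumerate_units(p$source, "segment")
  scored <- score_units(units, p$source, p$summary)
  ref <- document_tokens(p$summary)
  for (r in sample(nrow(scored), 25)) {
    toks <- unit_tokens(p$source$sentences[[scored$sentence_index[r]]],
                        scored$start[r], scored$end[r])
    expect_equal(scored$rouge2_f1[r], rouge_n(toks, ref, 2L)$f1)
  }
})

test_that("score_units hand fixture: bigram overlaps give the expected F1", {
  src <- document("s", list(mk_sent("a b c d e f", seg = c(2L, 4L))))
  ref <- document("r", list(mk_sent("a b x c d")))
  units <- enumerate_units(src, "segment")
  scored <- score_units(units, src, ref)
  # reference bigrams: ab, bx, xc, cd (4)
  # unit 1 "a b": 1 matching bigram of 1 -> P=1, R=1/4, F1=2/5
  expect_equal(scored$rouge2_f1[1], 2 * 1 * (1 / 4) / (1 + 1 / 4))
  # unit 2 "c d": bigram cd matches -> same score
  expect_equal(scored$rouge2_f1[2], 2 * 1 * (1 / 4) / (1 + 1 / 4))
  # unit 3 "e f": no match
  expect_equal(scored$rouge2_f1[3], 0)
  # empty-overlap reference: all zero
  ref0 <- document("r0", list(mk_sent("z9")))
  expect_true(all(score_units(units, src, ref0)$rouge2_f1 == 0))
})

test_that("assign_labels implements include-then-stop with document-order ties", {
  # 5 units, char_len 12 each, budget 30: cumulative 12, 24, 36 -> the third
  # selected unit overflows and is still included, then selection stops
  u <- data.frame(sentence_index = 1:5, start = 0L, end = 2L,
                  granularity = "segment", char_len = rep(12L, 5),
                  rouge2_f1 = c(0.9, 0.8, 0.7, 0.6, 0.5))
  lab <- assign_labels(u, budget_chars = 30L)
  expect_identical(lab$label, c(1L, 1L, 1L, 0L, 0L))
  # exclude-overflow variant stops before the third
  lab2 <- assign_labels(u, budget_chars = 30L, include_overflow = FALSE)
  expect_identical(lab2$label, c(1L, 1L, 0L, 0L, 0L))
  # all scores 0, tiny budget: first unit in document order wins
  u0 <- u; u0$rouge2_f1 <- 0
  lab0 <- assign_labels(u0, budget_chars = 5L)
  expect_identical(lab0$label, c(1L, 0L, 0L, 0L, 0L))
  # single unit below budget
  lab1 <- assign_labels(u[1, ], budget_chars = 100L)
  expect_identical(lab1$label, 1L)
  # positive char mass never exceeds budget + one unit
  set.seed(42)
  for (k in 1:30) {
    n <- sample(1:12, 1)
    uu <- data.frame(sentence_index = seq_len(n), start = 0L, end = 2L,
                     granularity = "segment",
                     char_len = sample(1:20, n, replace = TRUE),
                     rouge2_f1 = runif(n))
    budget <- sample(5:40, 1)
    ll <- assign_labels(uu, budget)
    expect_lte(sum(ll$char_len[ll$label == 1]),
               budget + max(ll$char_len))
  }
})

test_that("ranking is by score with ties broken by document order", {
  u <- data.frame(sentence_index = 1:4, start = 0L, end = 2L,
                  granularity = "segment", char_len = rep(10L, 4),
                  rouge2_f1 = c(0.5, 0.9, 0.5, 0.2))
  lab <- assign_labels(u, budget_chars = 15L)
  # 0.9 first (10), then the earliest 0.5 overflows and is included
  expect_identical(lab$label, c(1L, 1L, 0L, 0L))
})

test_that("split_dataset is disjoint, deterministic, and sized like the design", {
  corp <- desk_corpus(n_docs = 12, seed = 43)
  sp1 <- split_dataset(corp, 3, 4, seed = 2)
  sp2 <- split_dataset(corp, 3, 4, seed = 2)
  ids <- function(cc) vapply(cc, function(p) p$source$doc_id, character(1))
  expect_identical(ids(sp1$train), ids(sp2$train))
  expect_identical(ids(sp1$test), ids(sp2$test))
  expect_length(sp1$dev, 3L)
  expect_length(sp1$test, 4L)
  expect_length(sp1$train, 5L)
  all_ids <- c(ids(sp1$train), ids(sp1$dev), ids(sp1$test))
  expect_identical(sort(all_ids), sort(ids(corp)))
  expect_error(split_dataset(corp, 6, 6, seed = 1), "not enough")
  # archive-scale split arithmetic on a dummy corpus of 24,641 documents
  dummy_sent <- mk_sent("a b")
  dummy <- as_corpus(lapply(seq_len(24641), function(i)
    document_pair(document(paste0("d", i), list(dummy_sent)),
                  document(paste0("d", i, "-s"), list(dummy_sent)))))
  sp <- split_dataset(dummy, 1000, 1000, seed = 9)
  expect_length(sp$train, 22641L)
  expect_length(sp$dev, 1000L)
  expect_length(sp$test, 1000L)
})

test_that("oracle labels recover planted copies when the budget binds at the copy mass", {
  # planted-copy regime: every summary sentence is copied material, no
  # filler, no noise, so the reference is exactly the copied segments and
  # the per-document budget (its summary length) binds right at the end of
  # the copied set
  cfg <- generator_config(n_docs = 40, sentences_per_doc = 20,
                          summary_sentences = 10, summary_char_budget = 150,
                          copy_rate = 1, filler = FALSE,
                          noise_fullstop_drop_prob = 0,
                          noise_linebreak_prob = 0, seed = 44)
  corp <- generate_corpus(cfg)
  f1s <- vapply(corp, function(p) {
    units <- enumerate_units(p$source, "segment")
    scored <- score_units(units, p$source, p$summary)
    budget <- sum(vapply(p$summary$sentences, function(s)
      sum(s$tokens$char_len), numeric(1)))
    lab <- assign_labels(scored, budget)
    copied <- rep(FALSE, nrow(lab))
    for (r in seq_len(nrow(p$provenance))) {
      pv <- p$provenance[r, ]
      hit <- lab$sentence_index == pv$source_sent &
        lab$start == pv$source_start &
        (lab$end == pv$source_end | lab$end == pv$source_end + 1L)
      copied <- copied | hit
    }
    tp <- sum(lab$label == 1 & copied)
    prec <- if (sum(lab$label) > 0) tp / sum(lab$label) else 0
    rec <- if (sum(copied) > 0) tp / sum(copied) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  expect_gte(mean(f1s), 0.95)
})
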