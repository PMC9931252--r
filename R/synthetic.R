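# Synthetic parallel-corpus generator.
#
# Real discharge-summary corpora are access-restricted, so the pipeline is
# exercised on generated corpora that reproduce the statistical shape of the
# target archive: long source records (~192 sentences averaging ~9 tokens /
# ~18 characters), segment-structured sentences (~2.18 segments, i.e. ~1.18
# internal boundaries per sentence), summaries around 1,200 characters in
# which roughly a fifth to a third of sentences contain material copied
# verbatim from the source, and the typical noise of clinical free text
# (missing full stops, mid-sentence line breaks).
#
# Each source sentence is a concatenation of "medical event" templates; the
# template joins are the gold segment boundaries, and gold clause boundaries
# refine them by additionally splitting after particles.  Summaries copy
# source segments and recombine them into new sentences (possibly merging
# segments from different source sentences), mimicking how physicians lift
# concepts out of the record and reuse them in new contexts; this makes the
# segment the planted optimal granularity.  Segments vary in salience:
# salient events use a dedicated noun sub-vocabulary and are preferentially
# copied, so copy propensity is learnable from the tokens alone.

#' Configuration for the synthetic corpus generator
#'
#' Count distributions are shifted Poisson (minimum 1, or 2 for event
#' templates), parameterized by their mean.
#'
#' @param n_docs Number of document pairs.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param vocab_size Number of content word types.
#' @param sentences_per_doc Mean source sentences per document.
#' @param segments_per_sentence Mean segments (event templates) per source
#'   sentence.
#' @param tokens_per_segment Mean tokens per event template (minimum 2).
#' @param clause_subsplit_prob Probability that a clause boundary is added
#'   after each particle token inside a segment, so clause boundaries are a
#'   superset of segment boundaries.
#' @param copy_rate Probability that a summary sentence is built by copying
#'   source segments (the rest are filler); also, therefore, the expected
#'   fraction of summary sentences containing copied material.
#' @param summary_sentences Mean summary sentences per document.
#' @param summary_char_budget Maximum summary length in characters; assembly
#'   stops at the first sentence that exceeds it.
#' @param segments_per_copy_weights Probabilities of a copy sentence holding
#'   1, 2 or 3 copied segments.
#' @param salient_frac Fraction of event templates that are salient
#'   (drawn from the salient noun sub-vocabulary).
#' @param salience_weight Sampling weight of salient vs background segments
#'   when choosing what to copy.
#' @param filler If `FALSE`, non-copy summary sentences are skipped entirely
#'   (a single filler sentence is still emitted if a summary would otherwise
#'   be empty, since documents cannot be empty).
#' @param filler_vocab `"disjoint"` (default) draws filler nouns from a
#'   reserved vocabulary, so planted copies are essentially the only source
#'   of content n-gram matches between summary and source and the planted
#'   optimum is measurable; `"shared"` draws filler from the same background
#'   vocabulary as the source, adding realistic incidental n-gram overlap.
#' @param noise_fullstop_drop_prob Probability a sentence loses its trailing
#'   full stop.
#' @param noise_linebreak_prob Probability a sentence gains a line-break
#'   token at a random internal position.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_docs = 100L,
                             seed = 1L,
                             vocab_size = 500L,
                             sentences_per_doc = 192,
                             segments_per_sentence = 2.18,
                             tokens_per_segment = 3.7,
                             clause_subsplit_prob = 0.28,
                             copy_rate = 0.255,
                             summary_sentences = 35,
                             summary_char_budget = 1200L,
                             segments_per_copy_weights = c(0.4, 0.4, 0.2),
                             salient_frac = 0.3,
                             salience_weight = 9,
                             filler = TRUE,
                             filler_vocab = c("disjoint", "shared"),
                             noise_fullstop_drop_prob = 0.1,
                             noise_linebreak_prob = 0.05) {
  filler_vocab <- match.arg(filler_vocab)
  cfg <- list(n_docs = as.integer(n_docs), seed = as.integer(seed),
              vocab_size = as.integer(vocab_size),
              sentences_per_doc = sentences_per_doc,
              segments_per_sentence = segments_per_sentence,
              tokens_per_segment = tokens_per_segment,
              clause_subsplit_prob = clause_subsplit_prob,
              copy_rate = copy_rate,
              summary_sentences = summary_sentences,
              summary_char_budget = as.integer(summary_char_budget),
              segments_per_copy_weights = segments_per_copy_weights,
              salient_frac = salient_frac,
              salience_weight = salience_weight,
              filler = isTRUE(filler),
              filler_vocab = filler_vocab,
              noise_fullstop_drop_prob = noise_fullstop_drop_prob,
              noise_linebreak_prob = noise_linebreak_prob)
  probs <- c(cfg$clause_subsplit_prob, cfg$copy_rate,
             cfg$noise_fullstop_drop_prob, cfg$noise_linebreak_prob,
             cfg$salient_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  means <- c(cfg$sentences_per_doc, cfg$segments_per_sentence,
             cfg$summary_sentences)
  if (any(means <= 0) || cfg$tokens_per_segment < 2)
    stop("count means must be positive (tokens_per_segment >= 2)")
  if (cfg$n_docs < 1L || cfg$vocab_size < 20L || cfg$summary_char_budget < 1L)
    stop("infeasible config")
  if (abs(sum(cfg$segments_per_copy_weights) - 1) > 1e-8 ||
      length(cfg$segments_per_copy_weights) != 3L)
    stop("segments_per_copy_weights must be 3 probabilities summing to 1")
  structure(cfg, class = "generator_config")
}

# shifted Poisson with given mean and minimum
rcount <- function(n, mean, min = 1L) {
  min + stats::rpois(n, max(mean - min, 1e-9))
}

FULLSTOP <- "\u3002"
COMMA <- "\u3001"

# Deterministic word surfaces: unique lowercase strings averaging ~2 chars,
# so sentences land near 2 characters per token.
make_surfaces <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    w <- vapply(len, function(l)
      paste0(sample(letters, l, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

build_vocab <- function(cfg) {
  s <- make_surfaces(cfg$vocab_size + 100L)
  n_noun <- floor(cfg$vocab_size * 0.5)
  n_sal <- max(1L, floor(n_noun * cfg$salient_frac))
  n_part <- floor(cfg$vocab_size * 0.15)
  n_verb <- floor(cfg$vocab_size * 0.15)
  n_adj <- floor(cfg$vocab_size * 0.1)
  idx <- cumsum(c(n_noun, n_part, n_verb, n_adj))
  n_adv <- cfg$vocab_size - idx[4]
  nouns <- s[seq_len(n_noun)]
  list(
    noun_salient = nouns[seq_len(n_sal)],
    # last 10 nouns are reserved as verbal-noun boundary cues and never used
    # as interior nouns, so every terminal cue comes from a designated
    # boundary-cue vocabulary
    noun_background = nouns[(n_sal + 1L):(n_noun - 10L)],
    verbal_noun = nouns[(n_noun - 9L):n_noun],
    particle = s[(idx[1] + 1L):idx[2]],
    verb = s[(idx[2] + 1L):idx[3]],
    adjective = s[(idx[3] + 1L):idx[4]],
    adverb = s[(idx[4] + 1L):(idx[4] + n_adv)],
    filler_reserved = s[(cfg$vocab_size + 1L):(cfg$vocab_size + 100L)]
  )
}

# One "medical event" template: >= 2 tokens, ending in a cue token
# (predicate verb, comma, or verbal noun).
make_event <- function(cfg, vocab, salient, filler_pool = NULL) {
  len <- rcount(1L, cfg$tokens_per_segment, min = 2L)
  noun_pool <- if (!is.null(filler_pool)) filler_pool
               else if (salient) vocab$noun_salient else vocab$noun_background
  n_body <- len - 1L
  pos <- sample(c("noun", "particle", "adjective", "adverb"), n_body,
                replace = TRUE, prob = c(0.55, 0.3, 0.08, 0.07))
  surf <- character(n_body)
  for (p in c("noun", "particle", "adjective", "adverb")) {
    k <- pos == p
    if (any(k)) {
      pool <- switch(p, noun = noun_pool,
                     particle = vocab$particle,
                     adjective = vocab$adjective,
                     adverb = vocab$adverb)
      surf[k] <- sample(pool, sum(k), replace = TRUE)
    }
  }
  cue_kind <- sample(c("verb", "comma", "verbal_noun"), 1L,
                     prob = c(0.6, 0.25, 0.15))
  cue <- switch(cue_kind,
                verb = list(surface = sample(vocab$verb, 1L), pos = "verb"),
                comma = list(surface = COMMA, pos = "comma"),
                verbal_noun = list(surface = sample(vocab$verbal_noun, 1L),
                                   pos = "noun"))
  list(surface = c(surf, cue$surface), pos = c(pos, cue$pos),
       salient = salient)
}

# Assemble events into a sentence_record; gold segment boundaries at event
# joins, clause boundaries additionally after particles (internal only).
assemble_sentence <- function(cfg, events, add_fullstop = TRUE) {
  surf <- unlist(lapply(events, `[[`, "surface"), use.names = FALSE)
  pos <- unlist(lapply(events, `[[`, "pos"), use.names = FALSE)
  seg_bounds <- utils::head(cumsum(lengths(lapply(events, `[[`, "surface"))), -1L)
  if (add_fullstop) {
    surf <- c(surf, FULLSTOP)
    pos <- c(pos, "fullstop")
  }
  n <- length(surf)
  particle_after <- which(pos == "particle")  # boundary after token at index i -> position i
  particle_after <- particle_after[particle_after < n]
  extra <- particle_after[stats::runif(length(particle_after)) < cfg$clause_subsplit_prob]
  clause_bounds <- sort(unique(c(seg_bounds, extra)))
  sentence_record(surf, pos, seg_bounds = as.integer(seg_bounds),
                  clause_bounds = as.integer(clause_bounds))
}

# Apply noise in place to a document; returns list(doc, shifts) where shifts
# is a per-sentence insertion position (NA if none) for provenance fix-up.
apply_noise <- function(cfg, doc) {
  ins_pos <- rep(NA_integer_, length(doc$sentences))
  for (i in seq_along(doc$sentences)) {
    s <- doc$sentences[[i]]
    n <- nrow(s$tokens)
    surf <- s$tokens$surface; pos <- s$tokens$pos
    if (pos[n] == "fullstop" && n > 1L &&
        stats::runif(1) < cfg$noise_fullstop_drop_prob) {
      surf <- surf[-n]; pos <- pos[-n]
      n <- n - 1L
    }
    if (n > 1L && stats::runif(1) < cfg$noise_linebreak_prob) {
      p <- sample.int(n - 1L, 1L)  # insert between token p and p+1
      surf <- append(surf, "\n", after = p)
      pos <- append(pos, "linebreak", after = p)
      ins_pos[i] <- p
      shift <- function(b) ifelse(b > p, b + 1L, b)
      s$seg_bounds <- shift(s$seg_bounds)
      s$clause_bounds <- shift(s$clause_bounds)
    }
    doc$sentences[[i]] <- sentence_record(surf, pos, s$seg_bounds,
                                          s$clause_bounds)
  }
  list(doc = doc, ins_pos = ins_pos)
}

#' Generate a synthetic parallel corpus
#'
#' Produces `n_docs` source/summary pairs with gold segment and clause
#' boundaries and full provenance for every copied segment.  See
#' [generator_config()] for what is emulated.  Generation is deterministic
#' given the config (including its seed).
#'
#' @param cfg A [generator_config()].
#' @return A `granusum_corpus` whose pairs carry provenance data.frames.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  vocab <- build_vocab(cfg)
  pairs <- vector("list", cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    n_sent <- rcount(1L, cfg$sentences_per_doc)
    events_by_sent <- vector("list", n_sent)
    sents <- vector("list", n_sent)
    for (i in seq_len(n_sent)) {
      m <- rcount(1L, cfg$segments_per_sentence)
      evs <- lapply(seq_len(m), function(j)
        make_event(cfg, vocab, salient = stats::runif(1) < cfg$salient_frac))
      events_by_sent[[i]] <- evs
      sents[[i]] <- assemble_sentence(cfg, evs)
    }
    source_doc <- document(sprintf("doc%05d", d), sents)

    # pool of copyable segments: enumerate source units at segment granularity
    seg_units <- enumerate_units(source_doc, "segment")
    sal <- unlist(lapply(events_by_sent, function(evs)
      vapply(evs, `[[`, logical(1), "salient")), use.names = FALSE)
    # last unit of a sentence may include the trailing full stop; content
    # tokens for copying exclude it
    pool <- seg_units
    pool$weight <- ifelse(sal, cfg$salience_weight, 1)
    available <- rep(TRUE, nrow(pool))

    n_sum <- rcount(1L, cfg$summary_sentences)
    sum_sents <- list()
    prov <- list()
    total_chars <- 0L
    for (k in seq_len(n_sum)) {
      if (total_chars > cfg$summary_char_budget) break
      is_copy <- stats::runif(1) < cfg$copy_rate && any(available)
      if (is_copy) {
        g <- sample(1:3, 1L, prob = cfg$segments_per_copy_weights)
        idx_avail <- which(available)
        g <- min(g, length(idx_avail))
        take <- if (length(idx_avail) == 1L) idx_avail else
          sample(idx_avail, g, prob = pool$weight[idx_avail])
        if (length(take) > 1L) take <- sample(take)  # shuffle across source sentences
        available[take] <- FALSE
        events <- lapply(take, function(u) {
          sent <- source_doc$sentences[[pool$sentence_index[u]]]
          toks <- (pool$start[u] + 1L):pool$end[u]
          keep <- sent$tokens$pos[toks] != "fullstop"
          list(surface = sent$tokens$surface[toks][keep],
               pos = sent$tokens$pos[toks][keep], salient = NA)
        })
        ssent <- assemble_sentence(cfg, events)
        sum_sents[[length(sum_sents) + 1L]] <- ssent
        # provenance: spans of the copied *content* tokens (a trailing full
        # stop in the source segment is not copied and not referenced, so
        # spans stay valid if noise later deletes it)
        ev_len <- lengths(lapply(events, `[[`, "surface"))
        sum_starts <- c(0L, cumsum(ev_len))[seq_along(ev_len)]
        for (q in seq_along(take)) {
          u <- take[q]
          prov[[length(prov) + 1L]] <- data.frame(
            summary_sent = length(sum_sents),
            summary_start = sum_starts[q],
            summary_end = sum_starts[q] + ev_len[q],
            source_sent = pool$sentence_index[u],
            source_start = pool$start[u],
            source_end = pool$start[u] + ev_len[q])
        }
      } else {
        if (!cfg$filler) next
        m <- rcount(1L, cfg$segments_per_sentence)
        fp <- if (cfg$filler_vocab == "disjoint") vocab$filler_reserved else NULL
        evs <- lapply(seq_len(m), function(j)
          make_event(cfg, vocab, salient = FALSE, filler_pool = fp))
        ssent <- assemble_sentence(cfg, evs)
        sum_sents[[length(sum_sents) + 1L]] <- ssent
      }
      if (length(sum_sents))
        total_chars <- total_chars +
          sum(utils::tail(sum_sents, 1L)[[1]]$tokens$char_len)
    }
    if (!length(sum_sents)) {
      fp <- if (cfg$filler_vocab == "disjoint") vocab$filler_reserved else NULL
      sum_sents <- list(assemble_sentence(cfg, list(
        make_event(cfg, vocab, salient = FALSE, filler_pool = fp))))
    }
    summary_doc <- document(sprintf("doc%05d-s", d), sum_sents)
    prov_df <- if (length(prov)) do.call(rbind, prov) else NULL

    # noise; fix provenance for line-break insertions
    src_noised <- apply_noise(cfg, source_doc)
    source_doc <- src_noised$doc
    if (!is.null(prov_df)) {
      for (r in seq_len(nrow(prov_df))) {
        p <- src_noised$ins_pos[prov_df$source_sent[r]]
        if (!is.na(p)) {
          if (prov_df$source_start[r] >= p) {
            prov_df$source_start[r] <- prov_df$source_start[r] + 1L
            prov_df$source_end[r] <- prov_df$source_end[r] + 1L
          } else if (prov_df$source_end[r] > p) {
            prov_df$source_end[r] <- prov_df$source_end[r] + 1L
          }
        }
      }
    }
    smr_noised <- apply_noise(cfg, summary_doc)
    summary_doc <- smr_noised$doc
    if (!is.null(prov_df)) {
      for (r in seq_len(nrow(prov_df))) {
        p <- smr_noised$ins_pos[prov_df$summary_sent[r]]
        if (!is.na(p)) {
          if (prov_df$summary_start[r] >= p) {
            prov_df$summary_start[r] <- prov_df$summary_start[r] + 1L
            prov_df$summary_end[r] <- prov_df$summary_end[r] + 1L
          } else if (prov_df$summary_end[r] > p) {
            prov_df$summary_end[r] <- prov_df$summary_end[r] + 1L
          }
        }
      }
    }
    pairs[[d]] <- document_pair(source_doc, summary_doc, prov_df)
  }
  as_corpus(pairs)
}

#' Corpus-level descriptive statistics
#'
#' Arithmetic means over the corpus: document and sentence shape for source
#' and summary sides, and unit shape (units/sentence, tokens/unit,
#' characters/unit) per granularity using the gold boundary sets of all
#' documents (source and summary).
#'
#' @param corpus A `granusum_corpus` (non-empty).
#' @return A list with elements `cases`, `source`, `summary` (each a named
#'   numeric vector) and `units` (a data.frame with one row per granularity).
#' @export
corpus_statistics <- function(corpus) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  if (length(corpus) == 0L) stop("empty corpus")
  side_stats <- function(docs) {
    sent_per_doc <- vapply(docs, function(d) length(d$sentences), numeric(1))
    toks <- unlist(lapply(docs, function(d)
      vapply(d$sentences, function(s) nrow(s$tokens), numeric(1))))
    chars <- unlist(lapply(docs, function(d)
      vapply(d$sentences, function(s) sum(s$tokens$char_len), numeric(1))))
    c(sentences_per_doc = mean(sent_per_doc),
      tokens_per_sentence = mean(toks),
      chars_per_sentence = mean(chars),
      chars_per_doc = mean(vapply(docs, function(d)
        sum(vapply(d$sentences, function(s) sum(s$tokens$char_len),
                   numeric(1))), numeric(1))))
  }
  all_docs <- c(lapply(corpus, `[[`, "source"), lapply(corpus, `[[`, "summary"))
  unit_row <- function(gran) {
    us <- do.call(rbind, lapply(all_docs, enumerate_units, granularity = gran))
    n_sent <- sum(vapply(all_docs, function(d) length(d$sentences), numeric(1)))
    toks <- us$end - us$start
    data.frame(granularity = gran,
               units_per_sentence = nrow(us) / n_sent,
               tokens_per_unit = mean(toks),
               chars_per_unit = mean(us$char_len))
  }
  list(cases = length(corpus),
       source = side_stats(lapply(corpus, `[[`, "source")),
       summary = side_stats(lapply(corpus, `[[`, "summary")),
       units = do.call(rbind, lapply(c("sentence", "segment", "clause"),
                                     unit_row)))
}
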