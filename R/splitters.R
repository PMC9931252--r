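# Sub-sentence splitters and boundary evaluation.
#
# Three rule-based splitters (full stop; full stop & verb; a POS-cue clause
# splitter) and a trainable pointer-network segmenter.  All splitters return
# strictly increasing internal boundary positions (0-based, between tokens),
# so `enumerate_units()` over any splitter output partitions the sentence.

#' Rule-based splitter: full stops
#'
#' A boundary after every full-stop token that is not sentence-final.
#'
#' @param sent A [sentence_record()].
#' @return Integer vector of boundary positions (possibly empty).
#' @export
split_fullstop <- function(sent) {
  n <- nrow(sent$tokens)
  k <- which(sent$tokens$pos == "fullstop")
  as.integer(k[k < n])
}

#' Rule-based splitter: full stops and verbs
#'
#' All [split_fullstop()] boundaries plus, for each verb, a boundary
#' immediately in front of the next independent noun occurring after it
#' (non-independent nouns are skipped; a verb with no following noun
#' contributes nothing).
#'
#' @param sent A [sentence_record()].
#' @return Integer vector of boundary positions.
#' @export
split_fullstop_verb <- function(sent) {
  pos <- sent$tokens$pos
  n <- length(pos)
  b <- split_fullstop(sent)
  verbs <- which(pos == "verb")
  nouns <- which(pos == "noun")
  for (v in verbs) {
    j <- nouns[nouns > v]
    if (length(j)) {
      cand <- j[1L] - 1L        # boundary in front of token j
      if (cand >= 1L && cand <= n - 1L) b <- c(b, cand)
    }
  }
  sort(unique(as.integer(b)))
}

#' POS-cue clause splitter
#'
#' A simple stand-in for a full rule-based clause analyzer: a boundary after
#' every particle token and after every verb token (internal positions only).
#' Clauses in Japanese are short phrase-level units, often a noun plus a
#' particle, so particle/verb offsets approximate clause ends.
#'
#' @param sent A [sentence_record()].
#' @return Integer vector of boundary positions.
#' @export
split_clauses_pos <- function(sent) {
  pos <- sent$tokens$pos
  n <- length(pos)
  k <- which(pos %in% c("particle", "verb"))
  sort(unique(as.integer(k[k < n])))
}

#' Evaluate predicted boundaries against gold boundaries
#'
#' Exact-position matching of internal boundaries, micro-averaged over all
#' sentences: counts of true positives, false positives and false negatives
#' are pooled before computing precision, recall and F1 (each 0 when its
#' denominator is 0).
#'
#' @param predicted List of integer boundary vectors, one per sentence.
#' @param gold List of gold boundary vectors, aligned with `predicted`.
#' @return A list of class `boundary_eval` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_boundaries <- function(predicted, gold) {
  if (length(predicted) != length(gold))
    stop("predicted and gold must have the same number of sentences")
  tp <- fp <- fn <- 0L
  for (i in seq_along(gold)) {
    p <- unique(as.integer(predicted[[i]]))
    g <- unique(as.integer(gold[[i]]))
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1), class = "boundary_eval")
}

#' @export
print.boundary_eval <- function(x, ...) {
  cat(sprintf("<boundary_eval> P=%.3f R=%.3f F1=%.3f (TP=%d FP=%d FN=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pointer-network segmenter.
#
# Encoding: token vectors (word embedding for in-vocabulary tokens, plus a
# character n-gram composed embedding that also covers unknown words) run
# through a single-layer bidirectional tanh RNN.  Decoding: starting at the
# sentence start, the decoder state is derived from the encoder output at the
# first token of the current unit, and a pointer-attention scores every
# candidate end position in (current, sentence end]; the chosen end emits a
# boundary (unless sentence-final) and becomes the next unit's start, so the
# boundary sequence is strictly increasing and terminates at the sentence
# end.  Ties break toward the earliest position.

#' Configuration for the pointer-network segmenter
#'
#' @param embed_dim Token embedding width.
#' @param hidden Total encoder width (split across the two directions).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Sentences per gradient step.
#' @param ngram_buckets Hash buckets for character 3-5-gram composition.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `pointer_config`.
#' @export
pointer_config <- function(embed_dim = 32L, hidden = 64L, epochs = 20L,
                           lr = 5e-3, batch_size = 32L, ngram_buckets = 512L,
                           seed = 1L) {
  stopifnot(hidden %% 2 == 0, epochs >= 1, batch_size >= 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 ngram_buckets = as.integer(ngram_buckets),
                 seed = as.integer(seed)),
            class = "pointer_config")
}

# character n-gram hash buckets of a padded surface form (fastText-style
# composition without pretrained vectors)
char_ngram_buckets <- function(surface, buckets, nmin = 3L, nmax = 5L) {
  s <- paste0("<", surface, ">")
  cs <- utf8ToInt(s)
  L <- length(cs)
  out <- integer(0)
  for (n in nmin:min(nmax, L)) {
    for (i in seq_len(L - n + 1L)) {
      h <- 0
      for (c in cs[i:(i + n - 1L)]) h <- (h * 131 + c) %% buckets
      out <- c(out, h + 1L)
    }
  }
  if (!length(out)) out <- 1L
  out
}

# n x buckets row-normalized indicator matrix for n-gram composition
ngram_matrix <- function(surfaces, buckets) {
  n <- length(surfaces)
  S <- matrix(0, n, buckets)
  for (t in seq_len(n)) {
    b <- char_ngram_buckets(surfaces[t], buckets)
    for (x in b) S[t, x] <- S[t, x] + 1 / length(b)
  }
  S
}

pointer_params_init <- function(cfg, vocab_size) {
  d <- cfg$embed_dim; h <- cfg$hidden %/% 2L
  list(
    W_emb = init_mat(vocab_size + 1L, d, 0.1),  # last row: unknown-word slot
    G_emb = init_mat(cfg$ngram_buckets, d, 0.1),
    W_f = init_mat(d, h), U_f = init_mat(h, h), b_f = matrix(0, 1, h),
    W_b = init_mat(d, h), U_b = init_mat(h, h), b_b = matrix(0, 1, h),
    W_dec = init_mat(2L * h, 2L * h), b_dec = matrix(0, 1, 2L * h),
    W1 = init_mat(2L * h, 2L * h), W2 = init_mat(2L * h, 2L * h),
    v = init_mat(2L * h, 1L)
  )
}

token_indices <- function(surfaces, vocab) {
  idx <- vocab[surfaces]
  unk <- is.na(idx)
  idx[unk] <- length(vocab) + 1L
  list(idx = unname(idx), known = !unk)
}

# Numeric (tape-free) encoder for prediction
pointer_encode_numeric <- function(par, cfg, surfaces, vocab) {
  ti <- token_indices(surfaces, vocab)
  n <- length(surfaces)
  X <- par$W_emb[ti$idx, , drop = FALSE] * ti$known +
    ngram_matrix(surfaces, cfg$ngram_buckets) %*% par$G_emb
  h <- cfg$hidden %/% 2L
  Hf <- matrix(0, n, h); Hb <- matrix(0, n, h)
  prev <- matrix(0, 1, h)
  for (t in seq_len(n)) {
    prev <- tanh(X[t, , drop = FALSE] %*% par$W_f + prev %*% par$U_f + par$b_f)
    Hf[t, ] <- prev
  }
  prev <- matrix(0, 1, h)
  for (t in n:1) {
    prev <- tanh(X[t, , drop = FALSE] %*% par$W_b + prev %*% par$U_b + par$b_b)
    Hb[t, ] <- prev
  }
  cbind(Hf, Hb)
}

pointer_scores_numeric <- function(par, H, start_tok, candidates) {
  d <- tanh(H[start_tok, , drop = FALSE] %*% par$W_dec + par$b_dec)
  A <- tanh(sweep(H[candidates, , drop = FALSE] %*% par$W1, 2L,
                  (d %*% par$W2)[1L, ], `+`))
  as.vector(A %*% par$v)
}

# Tape-building forward over one sentence; returns loss node (teacher-forced)
pointer_sentence_loss <- function(params, cfg, surfaces, bounds, vocab) {
  n <- length(surfaces)
  ti <- token_indices(surfaces, vocab)
  mask <- matrix(rep(as.numeric(ti$known), cfg$embed_dim), n)
  Xw <- ad_mul(ad_rows(params$W_emb, ti$idx), ad_const(mask))
  Xg <- ad_matmul(ad_const(ngram_matrix(surfaces, cfg$ngram_buckets)),
                  params$G_emb)
  X <- ad_add(Xw, Xg)
  h <- cfg$hidden %/% 2L
  zero <- ad_const(matrix(0, 1, h))
  fwd <- vector("list", n); prev <- zero
  for (t in seq_len(n)) {
    prev <- ad_tanh(ad_add(ad_add(ad_matmul(ad_rows(X, t), params$W_f),
                                  ad_matmul(prev, params$U_f)), params$b_f))
    fwd[[t]] <- prev
  }
  bwd <- vector("list", n); prev <- zero
  for (t in n:1) {
    prev <- ad_tanh(ad_add(ad_add(ad_matmul(ad_rows(X, t), params$W_b),
                                  ad_matmul(prev, params$U_b)), params$b_b))
    bwd[[t]] <- prev
  }
  H <- ad_cbind(list(ad_rbind(fwd), ad_rbind(bwd)))
  starts <- c(0L, bounds)          # unit start positions, 0-based
  ends <- c(bounds, n)             # pointed end tokens, 1-based
  losses <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    cand <- (s + 1L):n
    dvec <- ad_tanh(ad_add(ad_matmul(ad_rows(H, s + 1L), params$W_dec),
                           params$b_dec))
    A <- ad_tanh(ad_add(ad_matmul(ad_rows(H, cand), params$W1),
                        ad_matmul(dvec, params$W2)))
    z <- ad_transpose(ad_matmul(A, params$v))   # 1 x k logits
    losses[[k]] <- ad_softmax_ce(z, match(ends[k], cand))
  }
  total <- losses[[1L]]
  if (length(losses) > 1L)
    for (k in 2L:length(losses)) total <- ad_add(total, losses[[k]])
  ad_scale(total, 1 / length(losses))
}

#' Train the pointer-network segmenter
#'
#' Minimizes per-step pointer cross-entropy with teacher forcing on the gold
#' segment boundaries.  Dev boundary F1 is computed each epoch and the
#' best-dev checkpoint is returned.  Training is deterministic given the
#' config seed.
#'
#' @param train List of [sentence_record()] with gold `seg_bounds`
#'   (non-empty).
#' @param dev List of [sentence_record()] used for checkpoint selection.
#' @param config A [pointer_config()].
#' @return An object of class `pointer_splitter`: list with `params`
#'   (numeric matrices), `vocab`, `config` and `history` (per-epoch loss and
#'   dev F1).
#' @export
train_pointer_splitter <- function(train, dev, config = pointer_config()) {
  if (!length(train)) stop("empty training set")
  stopifnot(inherits(config, "pointer_config"))
  set.seed(config$seed)
  surf_all <- unique(unlist(lapply(train, function(s) s$tokens$surface)))
  vocab <- stats::setNames(seq_along(surf_all), surf_all)
  par_val <- pointer_params_init(config, length(vocab))
  params <- lapply(par_val, ad_param)
  opt <- adam_init(params)
  best <- list(f1 = -1, params = NULL)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dev_f1 = numeric(0))
  gold_dev <- lapply(dev, `[[`, "seg_bounds")
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(train))
    ep_loss <- 0
    nb <- 0L
    for (batch_start in seq(1L, length(ord), by = config$batch_size)) {
      ids <- ord[batch_start:min(batch_start + config$batch_size - 1L,
                                 length(ord))]
      ad_zero_grad(params)
      for (i in ids) {
        s <- train[[i]]
        loss <- pointer_sentence_loss(params, config, s$tokens$surface,
                                      s$seg_bounds, vocab)
        ep_loss <- ep_loss + loss$val[1L]
        nb <- nb + 1L
        ad_backward(loss)
      }
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / length(ids)
      opt <- adam_step(opt, params, lr = config$lr)
    }
    snap <- lapply(params, function(p) p$val)
    model <- structure(list(params = snap, vocab = vocab, config = config),
                       class = "pointer_splitter")
    dev_f1 <- if (length(dev)) {
      pred <- lapply(dev, function(s) predict_boundaries(model, s))
      evaluate_boundaries(pred, gold_dev)$f1
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                         dev_f1 = dev_f1))
    if (!length(dev)) {
      best$params <- snap
    } else if (dev_f1 > best$f1) {
      # strict improvement keeps the earliest best epoch on ties
      best$f1 <- dev_f1
      best$params <- snap
    }
  }
  structure(list(params = best$params, vocab = vocab, config = config,
                 history = history), class = "pointer_splitter")
}

#' Predict segment boundaries with a trained pointer splitter
#'
#' Decodes greedily: each step points at the most probable end position among
#' the remaining candidates (ties to the earliest), yielding a strictly
#' increasing internal boundary set.  Unknown words are represented by their
#' character n-gram composition.
#'
#' @param model A `pointer_splitter`.
#' @param sent A [sentence_record()].
#' @return Integer vector of boundary positions.
#' @export
predict_boundaries <- function(model, sent) {
  stopifnot(inherits(model, "pointer_splitter"))
  surfaces <- sent$tokens$surface
  n <- length(surfaces)
  if (n <= 1L) return(integer(0))
  H <- pointer_encode_numeric(model$params, model$config, surfaces,
                              model$vocab)
  bounds <- integer(0)
  s <- 0L
  while (s < n) {
    cand <- (s + 1L):n
    sc <- pointer_scores_numeric(model$params, H, s + 1L, cand)
    j <- cand[which.max(sc)]
    if (j < n) bounds <- c(bounds, j)
    s <- j
  }
  bounds
}

#' Predict segment boundaries for every sentence of a document
#'
#' @param model A `pointer_splitter`.
#' @param doc A [document()].
#' @return List of integer boundary vectors, one per sentence.
#' @export
predict_document_boundaries <- function(model, doc) {
  lapply(doc$sentences, function(s) predict_boundaries(model, s))
}

#' Save / load a trained model
#'
#' Single-file serialization for `pointer_splitter` and `summarizer_model`
#' objects; a reloaded model produces identical outputs.
#'
#' @param model Model object.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
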