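# Unit-level extractive summarization model.
#
# One classification model covers all three granularities.  Tokens of each
# sentence (with begin-of-sentence and separator markers attached) are run
# through a small trainable self-attention encoder; each unit is then
# represented by average pooling of its member-token vectors — the markers
# are excluded from pooling, and at sentence granularity the begin-token
# vector is used directly with no pooling.  A unit-level self-attention
# layer over the document's unit sequence captures cross-unit context, and
# a sigmoid-affine head yields each unit's extraction probability.  Training
# minimizes binary cross-entropy against the oracle labels.
#
# The token encoder is deliberately pluggable in spirit: it stands where a
# pretrained masked-language-model encoder would sit, but trains from
# scratch so the pipeline runs on one CPU.

#' Configuration for the extractive summarizer
#'
#' @param hidden Model width (embedding and attention width).
#' @param enc_layers Self-attention layers in the token encoder.
#' @param unit_layers Self-attention layers over the unit sequence.
#' @param heads Attention heads per layer (must divide `hidden`).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_docs Documents per gradient step.
#' @param max_tokens Token window: documents are processed in chunks of
#'   whole sentences totalling at most this many tokens.
#' @param positional If `FALSE`, sinusoidal positional encodings are
#'   disabled and the forward pass is exactly permutation-equivariant at the
#'   unit level.
#' @param seed Integer seed for initialization and batch order.
#' @return A list of class `summarizer_config`.
#' @export
summarizer_config <- function(hidden = 64L, enc_layers = 2L, unit_layers = 1L,
                              heads = 2L, epochs = 10L, lr = 2e-3,
                              batch_docs = 4L, max_tokens = 512L,
                              positional = TRUE, seed = 1L) {
  stopifnot(hidden %% heads == 0, enc_layers >= 1, unit_layers >= 1)
  structure(list(hidden = as.integer(hidden),
                 enc_layers = as.integer(enc_layers),
                 unit_layers = as.integer(unit_layers),
                 heads = as.integer(heads), epochs = as.integer(epochs),
                 lr = lr, batch_docs = as.integer(batch_docs),
                 max_tokens = as.integer(max_tokens),
                 positional = isTRUE(positional), seed = as.integer(seed)),
            class = "summarizer_config")
}

# sinusoidal positional encoding matrix (constant)
posenc <- function(n, d) {
  if (n == 0L) return(matrix(0, 0L, d))
  pos <- seq_len(n) - 1L
  out <- matrix(0, n, d)
  for (k in seq_len(d %/% 2L)) {
    freq <- 1 / 10000^((2 * (k - 1)) / d)
    out[, 2L * k - 1L] <- sin(pos * freq)
    out[, 2L * k] <- cos(pos * freq)
  }
  out
}

attn_param_names <- function(prefix, layers, heads) {
  unlist(lapply(seq_len(layers), function(l) {
    c(vapply(seq_len(heads), function(h)
      paste0(prefix, l, "_h", h, "_", c("Wq", "Wk", "Wv")), character(3)),
      paste0(prefix, l, "_", c("Wo", "W1", "b1", "W2", "b2")))
  }))
}

summarizer_params_init <- function(cfg, vocab_size) {
  h <- cfg$hidden
  dk <- h %/% cfg$heads
  p <- list()
  p$W_emb <- init_mat(vocab_size + 3L, h, 0.1)  # + UNK, CLS, SEP rows
  mk_block <- function(prefix, layers) {
    for (l in seq_len(layers)) {
      for (hd in seq_len(cfg$heads)) {
        for (w in c("Wq", "Wk", "Wv"))
          p[[paste0(prefix, l, "_h", hd, "_", w)]] <<- init_mat(h, dk)
      }
      p[[paste0(prefix, l, "_Wo")]] <<- init_mat(h, h)
      p[[paste0(prefix, l, "_W1")]] <<- init_mat(h, h)
      p[[paste0(prefix, l, "_b1")]] <<- matrix(0, 1, h)
      p[[paste0(prefix, l, "_W2")]] <<- init_mat(h, h)
      p[[paste0(prefix, l, "_b2")]] <<- matrix(0, 1, h)
    }
  }
  mk_block("enc", cfg$enc_layers)
  mk_block("unit", cfg$unit_layers)
  p$W_out <- init_mat(h, 1L)
  p$b_out <- matrix(0, 1, 1)
  p
}

# one pre-norm-free transformer block: X + MHA(X), then + FFN
attn_block <- function(params, prefix, l, X, cfg) {
  dk <- cfg$hidden %/% cfg$heads
  heads <- lapply(seq_len(cfg$heads), function(hd) {
    q <- ad_matmul(X, params[[paste0(prefix, l, "_h", hd, "_Wq")]])
    k <- ad_matmul(X, params[[paste0(prefix, l, "_h", hd, "_Wk")]])
    v <- ad_matmul(X, params[[paste0(prefix, l, "_h", hd, "_Wv")]])
    a <- ad_softmax_rows(ad_scale(ad_matmul(q, ad_transpose(k)),
                                  1 / sqrt(dk)))
    ad_matmul(a, v)
  })
  mha <- ad_matmul(ad_cbind(heads), params[[paste0(prefix, l, "_Wo")]])
  X <- ad_add(X, mha)
  ff <- ad_matmul(ad_relu(ad_add(ad_matmul(X, params[[paste0(prefix, l, "_W1")]]),
                                 params[[paste0(prefix, l, "_b1")]])),
                  params[[paste0(prefix, l, "_W2")]])
  ad_add(X, ad_add(ff, params[[paste0(prefix, l, "_b2")]]))
}

sum_token_indices <- function(surfaces, vocab) {
  idx <- vocab[surfaces]
  idx[is.na(idx)] <- length(vocab) + 1L  # UNK row
  unname(idx)
}

# Forward pass over one chunk (a set of consecutive sentences and the units
# inside them).  Returns the logits node (n_units x 1).
summarizer_forward <- function(params, cfg, vocab, sentences, units) {
  V <- length(vocab)
  cls_row <- V + 2L
  sep_row <- V + 3L
  unit_encs <- vector("list", nrow(units))
  sent_ids <- sort(unique(units$sentence_index))
  for (si in sent_ids) {
    sent <- sentences[[si]]
    idx <- c(cls_row, sum_token_indices(sent$tokens$surface, vocab), sep_row)
    X <- ad_rows(params$W_emb, idx)
    if (cfg$positional)
      X <- ad_add(X, ad_const(posenc(length(idx), cfg$hidden)))
    for (l in seq_len(cfg$enc_layers))
      X <- attn_block(params, "enc", l, X, cfg)
    rows <- which(units$sentence_index == si)
    for (r in rows) {
      unit_encs[[r]] <- if (units$granularity[r] == "sentence") {
        ad_rows(X, 1L)
      } else {
        # +1 offsets the begin marker; markers never enter the pooling
        ad_mean_rows(ad_rows(X, (units$start[r] + 2L):(units$end[r] + 1L)))
      }
    }
  }
  U <- ad_rbind(unit_encs)
  if (cfg$positional)
    U <- ad_add(U, ad_const(posenc(nrow(units), cfg$hidden)))
  for (l in seq_len(cfg$unit_layers))
    U <- attn_block(params, "unit", l, U, cfg)
  ad_add(ad_matmul(U, params$W_out), params$b_out)
}

# split a document's units into chunks of whole sentences with at most
# cfg$max_tokens tokens (always at least one sentence per chunk)
chunk_units <- function(doc, units, max_tokens) {
  tok_per_sent <- vapply(doc$sentences, function(s) nrow(s$tokens), integer(1))
  sent_ids <- sort(unique(units$sentence_index))
  chunks <- list(); cur <- integer(0); cur_tok <- 0L
  for (si in sent_ids) {
    if (length(cur) && cur_tok + tok_per_sent[si] > max_tokens) {
      chunks[[length(chunks) + 1L]] <- cur
      cur <- integer(0); cur_tok <- 0L
    }
    cur <- c(cur, si); cur_tok <- cur_tok + tok_per_sent[si]
  }
  if (length(cur)) chunks[[length(chunks) + 1L]] <- cur
  lapply(chunks, function(ss) which(units$sentence_index %in% ss))
}

#' Encode document units into fixed-width vectors
#'
#' Runs the token encoder and pooling stage only (no unit-level attention):
#' each unit's encoding is the mean of its member-token vectors, except at
#' sentence granularity where the begin-token vector is used directly.
#' Mainly useful for inspection and testing; [predict_summary()] is the
#' full inference path.
#'
#' @param model A trained `summarizer_model` (or an untrained one from
#'   [train_summarizer()] internals).
#' @param doc A [document()].
#' @param units Unit data.frame partitioning `doc`.
#' @return Numeric matrix, one row per unit.
#' @export
encode_units <- function(model, doc, units) {
  cfg <- model$config
  params <- lapply(model$params, ad_const)
  vocab <- model$vocab
  V <- length(vocab)
  out <- matrix(0, nrow(units), cfg$hidden)
  for (si in sort(unique(units$sentence_index))) {
    sent <- doc$sentences[[si]]
    idx <- c(V + 2L, sum_token_indices(sent$tokens$surface, vocab), V + 3L)
    X <- ad_rows(params$W_emb, idx)
    if (cfg$positional)
      X <- ad_add(X, ad_const(posenc(length(idx), cfg$hidden)))
    for (l in seq_len(cfg$enc_layers))
      X <- attn_block(params, "enc", l, X, cfg)
    for (r in which(units$sentence_index == si)) {
      out[r, ] <- if (units$granularity[r] == "sentence") X$val[1L, ]
                  else colMeans(X$val[(units$start[r] + 2L):(units$end[r] + 1L),
                                      , drop = FALSE])
    }
  }
  out
}

#' Score units with the trained model
#'
#' Full forward pass: token encoding, unit pooling, unit-level
#' self-attention, sigmoid-affine head.
#'
#' @param model A `summarizer_model`.
#' @param doc A [document()].
#' @param units Unit data.frame partitioning `doc`.
#' @return Numeric vector of extraction probabilities in (0, 1).
#' @export
score_units_model <- function(model, doc, units) {
  cfg <- model$config
  params <- lapply(model$params, ad_const)
  probs <- numeric(nrow(units))
  for (rows in chunk_units(doc, units, cfg$max_tokens)) {
    z <- summarizer_forward(params, cfg, model$vocab, doc$sentences,
                            units[rows, , drop = FALSE])
    probs[rows] <- 1 / (1 + exp(-z$val[, 1L]))
  }
  probs
}

#' Train the extractive summarizer
#'
#' Minimizes mean binary cross-entropy between predicted unit probabilities
#' and the oracle labels.  After each epoch the model is evaluated on the
#' development set by mean ROUGE-1 F1 of its budgeted summaries, and the
#' best-dev checkpoint is returned.  Deterministic given the config seed.
#'
#' @param train_corpus,dev_corpus `granusum_corpus` objects.
#' @param train_labels,dev_labels Matching `labeled_corpus` objects from
#'   [oracle_label_corpus()].
#' @param config A [summarizer_config()].
#' @param budget_chars Budget used for dev-set summary generation
#'   (defaults to the labeling budget).
#' @param quiet Suppress per-epoch progress.
#' @return A `summarizer_model`: list with `params`, `vocab`, `config`,
#'   `granularity`, `history`.
#' @export
train_summarizer <- function(train_corpus, train_labels, dev_corpus = NULL,
                             dev_labels = NULL,
                             config = summarizer_config(),
                             budget_chars = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "summarizer_config"))
  if (!length(train_corpus)) stop("empty training set")
  if (length(train_labels$docs) != length(train_corpus))
    stop("label/corpus mismatch")
  for (i in seq_along(train_corpus)) {
    n_units <- nrow(train_labels$docs[[i]])
    if (is.null(n_units) || !n_units) stop("label/corpus mismatch")
  }
  budget_chars <- budget_chars %||% train_labels$budget_chars
  set.seed(config$seed)
  surf <- unique(unlist(lapply(train_corpus, function(p)
    lapply(p$source$sentences, function(s) s$tokens$surface))))
  vocab <- stats::setNames(seq_along(surf), surf)
  params <- lapply(summarizer_params_init(config, length(vocab)), ad_param)
  opt <- adam_init(params)
  best <- list(score = -Inf, params = lapply(params, function(p) p$val))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dev_rouge1 = numeric(0))
  n_docs <- length(train_corpus)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_docs)
    ep_loss <- 0; n_chunks <- 0L
    for (bs in seq(1L, n_docs, by = config$batch_docs)) {
      ids <- ord[bs:min(bs + config$batch_docs - 1L, n_docs)]
      ad_zero_grad(params)
      n_in_batch <- 0L
      for (i in ids) {
        doc <- train_corpus[[i]]$source
        lab <- train_labels$docs[[i]]
        for (rows in chunk_units(doc, lab, config$max_tokens)) {
          z <- summarizer_forward(params, config, vocab, doc$sentences,
                                  lab[rows, , drop = FALSE])
          loss <- ad_bce_with_logits(z, lab$label[rows])
          ep_loss <- ep_loss + loss$val[1L]; n_chunks <- n_chunks + 1L
          n_in_batch <- n_in_batch + 1L
          ad_backward(loss)
        }
      }
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / n_in_batch
      opt <- adam_step(opt, params, lr = config$lr)
    }
    snap <- lapply(params, function(p) p$val)
    model <- structure(list(params = snap, vocab = vocab, config = config,
                            granularity = train_labels$granularity),
                       class = "summarizer_model")
    dev_r1 <- NA_real_
    if (!is.null(dev_corpus) && length(dev_corpus)) {
      preds <- lapply(seq_along(dev_corpus), function(i)
        predict_summary(model, dev_corpus[[i]]$source,
                        units = dev_labels$docs[[i]],
                        budget_chars = budget_chars))
      ev <- evaluate_summaries(preds, lapply(dev_corpus, `[[`, "summary"))
      dev_r1 <- ev[["rouge1"]]
      if (dev_r1 > best$score) best <- list(score = dev_r1, params = snap)
    } else {
      best$params <- snap
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n_chunks,
                                         dev_rouge1 = dev_r1))
    if (!quiet)
      message(sprintf("epoch %d loss %.4f dev R1 %.2f", ep,
                      ep_loss / n_chunks, dev_r1))
  }
  structure(list(params = best$params, vocab = vocab, config = config,
                 granularity = train_labels$granularity, history = history),
            class = "summarizer_model")
}

#' Generate a budgeted extractive summary
#'
#' Units are ranked by predicted probability (ties broken by document
#' order) and selected greedily under the same include-then-stop character
#' budget rule used for oracle labeling; the selection is then re-sorted to
#' document order and concatenated.
#'
#' @param model A `summarizer_model`.
#' @param doc Source [document()].
#' @param units Unit data.frame (defaults to gold-boundary units at the
#'   model's granularity).
#' @param budget_chars Character budget (default 1200).
#' @param probs Optional externally supplied probabilities (e.g. oracle
#'   labels as an upper bound), bypassing the model forward pass.
#' @return List of class `summary_prediction`: `units` (selected rows with
#'   `prob`, document order), `unit_tokens` (list of token vectors),
#'   `tokens` (concatenated), `text`.
#' @export
predict_summary <- function(model, doc, units = NULL, budget_chars = 1200L,
                            probs = NULL) {
  if (is.null(units))
    units <- enumerate_units(doc, model$granularity)
  if (is.null(probs)) probs <- score_units_model(model, doc, units)
  stopifnot(length(probs) == nrow(units))
  sel <- greedy_select(probs, units$char_len, budget_chars)
  out <- units[sel, , drop = FALSE]
  out$prob <- probs[sel]
  out <- out[order(out$sentence_index, out$start), , drop = FALSE]
  toks <- lapply(seq_len(nrow(out)), function(r)
    unit_tokens(doc$sentences[[out$sentence_index[r]]], out$start[r],
                out$end[r]))
  structure(list(units = out, unit_tokens = toks,
                 tokens = unlist(toks, use.names = FALSE),
                 text = paste(vapply(toks, paste0, character(1),
                                     collapse = ""), collapse = " ")),
            class = "summary_prediction")
}

#' Evaluate predicted summaries against reference summaries
#'
#' Corpus-level mean of per-document ROUGE F1 scores, reported on the
#' conventional 0-100 scale.  ROUGE-L treats each selected unit as one
#' candidate sentence and each reference sentence as one reference sentence.
#'
#' @param predictions List of `summary_prediction` objects.
#' @param references List of reference [document()]s, aligned.
#' @return Named numeric vector `rouge1`, `rouge2`, `rougeL` (x100).
#' @export
evaluate_summaries <- function(predictions, references) {
  if (!length(predictions) || length(predictions) != length(references))
    stop("predictions and references must be non-empty and aligned")
  per_doc <- vapply(seq_along(predictions), function(i) {
    cand <- predictions[[i]]$tokens
    ref <- document_tokens(references[[i]])
    ref_sents <- lapply(references[[i]]$sentences, function(s)
      s$tokens$surface)
    c(rouge_n(cand, ref, 1L)$f1, rouge_n(cand, ref, 2L)$f1,
      rouge_l(ref_sents, predictions[[i]]$unit_tokens)$f1)
  }, numeric(3))
  100 * c(rouge1 = mean(per_doc[1L, ]), rouge2 = mean(per_doc[2L, ]),
          rougeL = mean(per_doc[3L, ]))
}
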