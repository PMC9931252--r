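# Domain types and corpus I/O.
#
# Conventions used throughout the package:
#   * Token positions are 0-based and unit spans are half-open [start, end),
#     so a sentence with n tokens spans [0, n).
#   * A boundary b is an internal split position, 0 < b < n, sitting between
#     token b-1 and token b.  The sentence-final position is never stored.
#   * Sentence indices inside a document are 1-based (ordinary R indexing).

#' Part-of-speech tags understood by the package
#'
#' A fixed coarse tag set sufficient for the rule-based splitters: nouns
#' (independent and non-independent), verbs, particles, adjectives, adverbs,
#' punctuation (full stop, comma, parentheses), line breaks and a catch-all.
#'
#' @return Character vector of valid tags.
#' @export
pos_tags <- function() {
  c("noun", "noun_nonindependent", "verb", "particle", "adjective",
    "adverb", "fullstop", "comma", "paren_open", "paren_close",
    "linebreak", "other")
}

#' Construct a tokenized sentence record
#'
#' A sentence is a sequence of pre-tokenized surface forms with coarse POS
#' tags, plus (optionally) gold segment and clause boundary sets.  Boundaries
#' are internal 0-based positions: boundary `b` separates token `b-1` from
#' token `b`, so valid values are `1 .. n_tokens-1`.
#'
#' @param surface Character vector of token surface forms (non-empty strings).
#' @param pos Character vector of POS tags, one per token (see [pos_tags()]).
#' @param seg_bounds Integer vector of gold segment boundaries (may be empty).
#' @param clause_bounds Integer vector of gold clause boundaries (may be empty).
#' @return An object of class `sentence_record`: a list with elements
#'   `tokens` (data.frame with columns `surface`, `pos`, `char_len`),
#'   `seg_bounds`, `clause_bounds` and `raw` (concatenated surfaces).
#' @export
sentence_record <- function(surface, pos, seg_bounds = integer(0),
                            clause_bounds = integer(0)) {
  stopifnot(is.character(surface), length(surface) >= 1L,
            length(surface) == length(pos))
  if (any(!nzchar(surface))) stop("token surfaces must be non-empty")
  bad <- setdiff(unique(pos), pos_tags())
  if (length(bad)) stop("unknown POS tag(s): ", paste(bad, collapse = ", "))
  n <- length(surface)
  seg_bounds <- validate_boundaries(seg_bounds, n, "seg_bounds")
  clause_bounds <- validate_boundaries(clause_bounds, n, "clause_bounds")
  structure(list(
    tokens = data.frame(surface = surface, pos = pos,
                        char_len = nchar(surface), stringsAsFactors = FALSE),
    seg_bounds = seg_bounds,
    clause_bounds = clause_bounds,
    raw = paste0(surface, collapse = "")
  ), class = "sentence_record")
}

validate_boundaries <- function(b, n_tokens, what = "boundaries") {
  if (length(b) == 0L) return(integer(0))
  b <- as.integer(b)
  if (anyNA(b)) stop(what, ": NA boundary")
  if (any(b <= 0L) || any(b >= n_tokens))
    stop(what, ": boundaries must be internal positions in (0, ", n_tokens, ")")
  if (is.unsorted(b, strictly = TRUE))
    stop(what, ": boundaries must be strictly increasing")
  b
}

#' @export
print.sentence_record <- function(x, ...) {
  cat("<sentence_record> ", nrow(x$tokens), " tokens, ",
      length(x$seg_bounds), " seg / ", length(x$clause_bounds),
      " clause bounds: ", x$raw, "\n", sep = "")
  invisible(x)
}

#' Construct a document
#'
#' @param doc_id Unique document identifier.
#' @param sentences List of [sentence_record()] objects (at least one).
#' @return Object of class `document`.
#' @export
document <- function(doc_id, sentences) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.list(sentences) || length(sentences) < 1L)
    stop("a document needs at least one sentence")
  ok <- vapply(sentences, inherits, logical(1), "sentence_record")
  if (!all(ok)) stop("all sentences must be sentence_record objects")
  structure(list(doc_id = doc_id, sentences = sentences), class = "document")
}

#' Construct a source/summary document pair
#'
#' @param source A [document()]: the full record (e.g. inpatient notes).
#' @param summary A [document()]: the reference summary (e.g. discharge
#'   summary).
#' @param provenance Optional data.frame mapping copied summary spans back to
#'   source spans, with columns `summary_sent`, `summary_start`, `summary_end`,
#'   `source_sent`, `source_start`, `source_end` (sentence indices 1-based,
#'   token spans half-open 0-based).  Only synthetic corpora carry provenance.
#' @return Object of class `document_pair`.
#' @export
document_pair <- function(source, summary, provenance = NULL) {
  stopifnot(inherits(source, "document"), inherits(summary, "document"))
  if (!is.null(provenance)) {
    need <- c("summary_sent", "summary_start", "summary_end",
              "source_sent", "source_start", "source_end")
    if (!is.data.frame(provenance) || !all(need %in% names(provenance)))
      stop("provenance must be a data.frame with columns ",
           paste(need, collapse = ", "))
    provenance <- provenance[, need, drop = FALSE]
    check_span <- function(doc, sent, s, e, side) {
      n_sent <- length(doc$sentences)
      if (any(sent < 1L | sent > n_sent))
        stop("provenance: ", side, " sentence index out of range")
      len <- vapply(doc$sentences, function(x) nrow(x$tokens), integer(1))[sent]
      if (any(s < 0L | e > len | s >= e))
        stop("provenance: ", side, " span out of range")
    }
    check_span(summary, provenance$summary_sent, provenance$summary_start,
               provenance$summary_end, "summary")
    check_span(source, provenance$source_sent, provenance$source_start,
               provenance$source_end, "source")
  }
  structure(list(source = source, summary = summary, provenance = provenance),
            class = "document_pair")
}

#' Bundle document pairs into a corpus
#'
#' @param pairs List of [document_pair()] objects.
#' @return Object of class `granusum_corpus` (a list of pairs).
#' @export
as_corpus <- function(pairs) {
  ok <- vapply(pairs, inherits, logical(1), "document_pair")
  if (!all(ok)) stop("all elements must be document_pair objects")
  ids <- vapply(pairs, function(p) p$source$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus")
  structure(pairs, class = "granusum_corpus")
}

#' @export
print.granusum_corpus <- function(x, ...) {
  cat("<granusum_corpus> ", length(x), " document pairs\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sentence splitting of raw noisy text

#' Split raw text into sentences
#'
#' Clinical free text is noisy: full stops are often missing and line breaks
#' appear mid-sentence.  Two naive rules define a sentence boundary, applied
#' greedily left to right: (a) a sentence ends at every full-stop character
#' (which stays part of the sentence); (b) a statement followed by a line
#' break with no full stop ends at that line break.  Line-break characters
#' are never part of the output (a break directly after a full stop, at the
#' start of the text, or doubled, is simply dropped), so concatenating the
#' output sentences plus the removed break characters reproduces the input.
#'
#' @param raw_text A single string, possibly containing full stops and line
#'   breaks.
#' @param fullstop_chars Characters treated as full stops
#'   (default the ideographic full stop, `"\u3002"`).
#' @return Character vector of sentences, in order, with no empty entries.
#'   An empty input yields `character(0)`.
#' @export
split_sentences <- function(raw_text, fullstop_chars = "\u3002") {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  chars <- strsplit(raw_text, "", fixed = FALSE)[[1]]
  is_nl <- chars == "\n"
  ends_sentence <- chars %in% fullstop_chars | is_nl
  # sentence id grows right after every terminator
  sid <- cumsum(c(0L, utils::head(as.integer(ends_sentence), -1L)))
  keep <- !is_nl
  if (!any(keep)) return(character(0))
  out <- vapply(split(chars[keep], sid[keep]), paste0, character(1),
                collapse = "")
  out <- unname(out[nzchar(out)])
  out
}

# ---------------------------------------------------------------------------
# Unit enumeration

#' Enumerate extraction units of a document at a given granularity
#'
#' Units partition every sentence: at `"sentence"` granularity each sentence
#' is one unit; at `"segment"` or `"clause"` granularity each sentence is cut
#' at its boundary set into consecutive spans.
#'
#' @param doc A [document()].
#' @param granularity One of `"sentence"`, `"segment"`, `"clause"`.
#' @param boundaries Optional list of integer boundary vectors, one per
#'   sentence, overriding the gold boundaries stored in the document (ignored
#'   for sentence granularity).
#' @return A data.frame with one row per unit and columns `sentence_index`
#'   (1-based), `start`, `end` (0-based half-open token span), `granularity`
#'   and `char_len`, in document order.
#' @export
enumerate_units <- function(doc, granularity = c("sentence", "segment", "clause"),
                            boundaries = NULL) {
  stopifnot(inherits(doc, "document"))
  granularity <- match.arg(granularity)
  n_sent <- length(doc$sentences)
  if (!is.null(boundaries) && length(boundaries) != n_sent)
    stop("boundaries must have one entry per sentence")
  rows <- vector("list", n_sent)
  for (i in seq_len(n_sent)) {
    sent <- doc$sentences[[i]]
    n <- nrow(sent$tokens)
    b <- if (granularity == "sentence") {
      integer(0)
    } else if (!is.null(boundaries)) {
      validate_boundaries(boundaries[[i]], n)
    } else if (granularity == "segment") {
      sent$seg_bounds
    } else {
      sent$clause_bounds
    }
    starts <- c(0L, b)
    ends <- c(b, n)
    cl <- cumsum(sent$tokens$char_len)
    char_len <- cl[ends] - c(0L, cl)[starts + 1L]
    rows[[i]] <- data.frame(sentence_index = i, start = starts, end = ends,
                            granularity = granularity, char_len = char_len)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the token surfaces of a unit
#'
#' @param sent A [sentence_record()].
#' @param start,end Half-open 0-based token span.
#' @return Character vector of surfaces.
#' @export
unit_tokens <- function(sent, start, end) {
  sent$tokens$surface[(start + 1L):end]
}

#' All token surfaces of a document, in order
#'
#' @param doc A [document()].
#' @return Character vector.
#' @export
document_tokens <- function(doc) {
  unlist(lapply(doc$sentences, function(s) s$tokens$surface), use.names = FALSE)
}

#' Reconstruct the raw text of a document
#'
#' Sentences are joined with line breaks, mirroring how records are stored
#' as plain text.
#'
#' @param doc A [document()].
#' @return Single string.
#' @export
document_raw <- function(doc) {
  paste(vapply(doc$sentences, function(s) s$raw, character(1)),
        collapse = "\n")
}

# ---------------------------------------------------------------------------
# Corpus file I/O: UTF-8 JSON lines, one document pair per line.

sentence_to_list <- function(sent) {
  list(
    tokens = lapply(seq_len(nrow(sent$tokens)), function(k) {
      list(surface = sent$tokens$surface[k], pos = sent$tokens$pos[k])
    }),
    seg_bounds = as.integer(sent$seg_bounds),
    clause_bounds = as.integer(sent$clause_bounds)
  )
}

sentence_from_list <- function(x) {
  surfaces <- vapply(x$tokens, function(t) t$surface, character(1))
  pos <- vapply(x$tokens, function(t) t$pos, character(1))
  sentence_record(surfaces, pos,
                  seg_bounds = unlist(x$seg_bounds, use.names = FALSE) %||% integer(0),
                  clause_bounds = unlist(x$clause_bounds, use.names = FALSE) %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pair_to_json <- function(pair) {
  x <- list(
    doc_id = pair$source$doc_id,
    source = lapply(pair$source$sentences, sentence_to_list),
    summary = lapply(pair$summary$sentences, sentence_to_list)
  )
  if (!is.null(pair$provenance)) x$provenance <- pair$provenance
  jsonlite::toJSON(x, auto_unbox = TRUE, dataframe = "rows", digits = NA)
}

pair_from_list <- function(x) {
  if (is.null(x$doc_id) || is.null(x$source) || is.null(x$summary))
    stop("record must have doc_id, source and summary")
  src <- document(x$doc_id, lapply(x$source, sentence_from_list))
  smr <- document(paste0(x$doc_id, "-summary"),
                  lapply(x$summary, sentence_from_list))
  prov <- NULL
  if (!is.null(x$provenance) && length(x$provenance)) {
    prov <- do.call(rbind, lapply(x$provenance, function(r)
      as.data.frame(r[c("summary_sent", "summary_start", "summary_end",
                        "source_sent", "source_start", "source_end")])))
    prov[] <- lapply(prov, as.integer)
  }
  document_pair(src, smr, prov)
}

#' Write a corpus to a JSON-lines file
#'
#' One document pair per line; canonical field order so that
#' [read_corpus()] followed by [write_corpus()] is byte-identical.
#'
#' @param corpus A `granusum_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  lines <- vapply(corpus, function(p) as.character(pair_to_json(p)), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a JSON-lines file
#'
#' @param path Input file path (UTF-8 JSON lines, one document pair each).
#' @return A `granusum_corpus`.  Malformed lines raise an error naming the
#'   line number; an empty file yields an empty corpus.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  pairs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) stop("line ", i, ": malformed JSON (",
                                           conditionMessage(e), ")", call. = FALSE))
    pairs[[i]] <- tryCatch(pair_from_list(x),
                           error = function(e) stop("line ", i, ": ",
                                                    conditionMessage(e), call. = FALSE))
  }
  as_corpus(pairs)
}

#' Validate a corpus object
#'
#' Re-checks every structural invariant: boundary ranges and ordering,
#' non-empty sentences, raw-text reconstruction, provenance span validity and
#' doc_id uniqueness.  Construction already enforces these; this is the
#' explicit entry point for corpora read from disk or built by hand.
#'
#' @param corpus A `granusum_corpus`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "granusum_corpus"))
  for (p in corpus) {
    for (doc in list(p$source, p$summary)) {
      for (s in doc$sentences) {
        n <- nrow(s$tokens)
        validate_boundaries(s$seg_bounds, n, paste0(doc$doc_id, " seg_bounds"))
        validate_boundaries(s$clause_bounds, n, paste0(doc$doc_id, " clause_bounds"))
        if (!identical(s$raw, paste0(s$tokens$surface, collapse = "")))
          stop(doc$doc_id, ": raw text does not reconstruct from tokens")
      }
    }
    # re-run provenance checks
    document_pair(p$source, p$summary, p$provenance)
  }
  invisible(TRUE)
}
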