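# Sentence segmentation and sentence-bound filtering.

# Abbreviations that never end a sentence (matched case-insensitively
# against the token preceding the period, without the period itself).
.default_abbreviations <- c(
  "e.g", "i.e", "vs", "cf", "al", "et", "fig", "figs", "spp", "sp",
  "subsp", "no", "ca", "approx"
)

#' Segment a document into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or
#' `?` followed by whitespace (or end of text), unless the preceding token
#' is a known abbreviation or a single capital initial (as in abbreviated
#' genus names, "B. longum").  A boundary that would split an annotated
#' mention is moved past that mention.  The resulting boundaries partition
#' the text.
#'
#' @param doc A [standoff_document()].
#' @param abbreviations Character vector of abbreviation tokens (without
#'   the trailing period).
#' @return The document with its `sentences` tibble (`start`, `end`;
#'   0-based half-open) filled in.
#' @export
segment_sentences <- function(doc, abbreviations = .default_abbreviations) {
  text <- doc$text
  n <- nchar(text)
  if (n == 0L) stop("cannot segment an empty document", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]

  is_term <- chars %in% c(".", "!", "?")
  ends <- integer() # candidate sentence ends, 0-based half-open (offset after terminator)
  for (i in which(is_term)) {
    after_ok <- i == n || grepl("^\\s", substring(text, i + 1L, i + 1L))
    if (!after_ok) next
    if (chars[i] == ".") {
      prev <- sub(".*?([A-Za-z][A-Za-z.]*)$", "\\1", substring(text, max(1L, i - 12L), i - 1L))
      tok <- tolower(prev)
      if (tok %in% abbreviations) next
      if (grepl("^[A-Z]$", prev)) next # genus initial "B."
    }
    ends <- c(ends, i) # 0-based: terminator at 0-based i-1, boundary after it = i
  }
  # never split inside an annotated mention envelope
  mentions <- rbind(
    if (nrow(doc$entities)) t(vapply(doc$entities$fragments, span_envelope, integer(2L))),
    if (nrow(doc$triggers)) t(vapply(doc$triggers$fragments, span_envelope, integer(2L)))
  )
  if (!is.null(mentions) && nrow(mentions) > 0L && length(ends)) {
    ends <- vapply(ends, function(b) {
      repeat {
        inside <- mentions[, 1L] < b & b < mentions[, 2L]
        if (!any(inside)) return(b)
        b <- max(mentions[inside, 2L])
      }
    }, integer(1L))
    ends <- sort(unique(ends))
  }
  ends <- ends[ends < n]
  starts <- c(0L, ends)
  stops <- c(ends, n)
  keep <- starts < stops
  doc$sentences <- tibble(start = starts[keep], end = stops[keep])
  doc
}

# 1-based sentence index containing a span's envelope, or NA if the span
# crosses a sentence boundary.
sentence_index <- function(sentences, frags) {
  env <- span_envelope(frags)
  hit <- which(sentences$start <= env[1L] & env[2L] <= sentences$end)
  if (length(hit) == 1L) hit else NA_integer_
}

mention_sentence_index <- function(doc, tb) {
  if (nrow(tb) == 0L) return(integer())
  vapply(tb$fragments, function(fr) sentence_index(doc$sentences, fr), integer(1L))
}

#' Mark or drop relations that are not sentence-bound
#'
#' A relation is sentence-bound when its argument mentions (and its
#' trigger, if any) all fall inside one sentence.  Cross-sentence
#' relations are substantially harder to model and are excluded from
#' training and evaluation by the fine-tuned pipeline; entities are left
#' untouched.
#'
#' @param doc A segmented [standoff_document()].
#' @param drop If `TRUE` (default) cross-sentence relations are removed;
#'   otherwise they are only flagged via the `sentence_bound` column.
#' @return The document with relations flagged and optionally filtered.
#' @export
filter_sentence_bound <- function(doc, drop = TRUE) {
  if (is.null(doc$sentences)) stop("segment sentences first", call. = FALSE)
  if (nrow(doc$relations) == 0L) return(doc)
  ent_sent <- stats::setNames(mention_sentence_index(doc, doc$entities),
                              doc$entities$id)
  trg_sent <- stats::setNames(mention_sentence_index(doc, doc$triggers),
                              doc$triggers$id)
  lookup <- c(ent_sent, trg_sent)
  bound <- vapply(seq_len(nrow(doc$relations)), function(i) {
    r <- doc$relations[i, ]
    members <- c(r$agent, r$theme1, r$theme2, r$trigger)
    members <- members[!is.na(members)]
    sents <- lookup[members]
    !anyNA(sents) && length(unique(sents)) == 1L
  }, logical(1L))
  doc$relations$sentence_bound <- bound
  if (drop) doc$relations <- doc$relations[bound, ]
  doc
}

# ---- word tokenization ------------------------------------------------------

# Whitespace/punctuation word tokenizer with character offsets.  Returns a
# tibble (token, start, end) with 0-based half-open offsets.  Hyphens
# inside words are kept (entity surfaces like "ox-ldl" stay one token).
tokenize_words <- function(text, from = 0L, to = nchar(text)) {
  seg <- substring(text, from + 1L, to)
  ml <- gregexpr("[A-Za-z0-9_'-]+|[^A-Za-z0-9_'\\s-]", seg, perl = TRUE)
  m <- ml[[1L]]
  if (m[1L] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L + from
  lens <- attr(m, "match.length")
  tibble(token = regmatches(seg, ml)[[1L]],
         start = starts, end = starts + lens)
}

# Tokens per sentence of a segmented document: list of token tibbles.
sentence_tokens <- function(doc) {
  if (is.null(doc$sentences)) stop("segment sentences first", call. = FALSE)
  lapply(seq_len(nrow(doc$sentences)), function(i) {
    tokenize_words(doc$text, doc$sentences$start[i], doc$sentences$end[i])
  })
}

# Map a character span (envelope) to inclusive word-token indices within a
# sentence token table; NA if the span does not align with any token.
char_span_to_tokens <- function(tokens, start, end) {
  ov <- which(tokens$start < end & start < tokens$end)
  if (length(ov) == 0L) return(c(NA_integer_, NA_integer_))
  c(min(ov), max(ov))
}
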