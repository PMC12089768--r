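# Entity and trigger recognition as span classification.  One joint head
# over a 29-way label space (15 entity types + 13 trigger types + null):
# entity and trigger candidate spans share the same maximum span length
# and a single feedforward layer recognizes both.

#' Training configuration for the span tagger and relation models
#'
#' @param max_span_length Maximum candidate span width in word tokens.
#' @param cap Maximum levitated marker pairs per pack.
#' @param epochs,lr,momentum,l2 Gradient-descent settings for the
#'   classification head (cross-entropy objective).
#' @param class_weight_alpha Class-balancing exponent in `[0, 1]` for the
#'   head's per-sample weights (0 = unweighted, 1 = fully balanced).
#' @param seed Training seed (head initialisation).
#' @param sections Sections used for training.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_span_length = 8L, cap = 30L, epochs = 250L,
                         lr = 1, momentum = 0.9, l2 = 1e-4,
                         class_weight_alpha = 0.5, seed = 42L,
                         sections = c("title_abstract", "results")) {
  structure(list(max_span_length = as.integer(max_span_length),
                 cap = as.integer(cap), epochs = as.integer(epochs),
                 lr = lr, momentum = momentum, l2 = l2,
                 class_weight_alpha = class_weight_alpha,
                 seed = as.integer(seed), sections = sections),
            class = "train_config")
}

# Default seeds for multi-run experiments (means over 5 training runs).
#' Default training seeds
#' @return Integer vector of the five default run seeds.
#' @export
default_seeds <- function() c(13L, 21L, 42L, 87L, 100L)

# ---- sentence views ---------------------------------------------------------

# Per-sentence view of a document: tokens plus gold mentions mapped to
# word-token spans (0-based inclusive).  Discontinuous mentions are
# collapsed to their minimal covering contiguous span for candidate
# generation; exact fragments are kept in I/O and used for evaluation.
doc_sentence_views <- function(doc) {
  if (is.null(doc$sentences)) doc <- segment_sentences(doc)
  toks <- sentence_tokens(doc)
  map_tb <- function(tb, sent_ix) {
    views <- vector("list", length(toks))
    for (k in seq_along(views)) views[[k]] <-
        tibble(id = character(), type = character(),
               start = integer(), end = integer())
    if (nrow(tb) == 0L) return(views)
    for (i in seq_len(nrow(tb))) {
      si <- sent_ix[i]
      if (is.na(si)) next
      env <- span_envelope(tb$fragments[[i]])
      rng <- char_span_to_tokens(toks[[si]], env[1L], env[2L])
      if (anyNA(rng)) next
      views[[si]] <- dplyr::bind_rows(
        views[[si]],
        tibble(id = tb$id[i], type = tb$type[i],
               start = rng[1L] - 1L, end = rng[2L] - 1L))
    }
    views
  }
  ent_sent <- mention_sentence_index(doc, doc$entities)
  trg_sent <- mention_sentence_index(doc, doc$triggers)
  lapply(seq_along(toks), function(si) {
    list(tokens = toks[[si]],
         entities = map_tb(doc$entities, ent_sent)[[si]],
         triggers = map_tb(doc$triggers, trg_sent)[[si]],
         sentence = si)
  })
}

# ---- dataset ----------------------------------------------------------------

# Enumerate, pack and encode all candidate spans of a corpus; label each
# span with its gold entity or trigger type (null "O" otherwise).
build_ner_dataset <- function(corpus, encoder, config) {
  X <- list(); y <- list()
  for (doc in corpus) {
    if (!doc$section %in% config$sections) next
    for (view in doc_sentence_views(doc)) {
      n <- nrow(view$tokens)
      if (n == 0L) next
      cands <- enumerate_spans(n, config$max_span_length)
      gold <- dplyr::bind_rows(view$entities, view$triggers)
      key <- paste(cands$start, cands$end)
      lab <- rep("O", nrow(cands))
      if (nrow(gold) > 0L) {
        gk <- paste(gold$start, gold$end)
        hit <- match(key, gk)
        lab[!is.na(hit)] <- gold$type[hit[!is.na(hit)]]
      }
      packs <- pack_neighborhood(view$tokens$token, cands, config$cap)
      off <- 0L
      for (pk in packs) {
        enc <- encode_pack(encoder, pk)
        R <- span_features(lev_representations(enc, pk), encoder$width)
        X[[length(X) + 1L]] <- R
        y[[length(y) + 1L]] <- lab[off + seq_len(nrow(R))]
        off <- off + nrow(R)
      }
    }
  }
  list(X = do.call(rbind, X), y = unlist(y))
}

# ---- training ---------------------------------------------------------------

#' Train the joint entity/trigger span tagger
#'
#' Minimizes cross-entropy over all enumerated candidate spans of the
#' training sections: the gold label for annotated spans (entity type or
#' trigger type), null otherwise.  The per-epoch training loss is kept in
#' the returned model.
#'
#' @param corpus List of validated, segmented [standoff_document()]s.
#' @param encoder A [frozen_encoder()].
#' @param config A [train_config()].
#' @param schema An [default_schema()] object.
#' @return A `span_tagger` model object.
#' @export
train_span_tagger <- function(corpus, encoder, config = train_config(),
                              schema = default_schema()) {
  corpus <- Filter(function(d) d$section %in% config$sections, corpus)
  if (length(corpus) == 0L) stop("empty training set", call. = FALSE)
  ds <- build_ner_dataset(corpus, encoder, config)
  if (is.null(ds$X) || nrow(ds$X) == 0L) stop("empty training set", call. = FALSE)
  labels <- c(schema$entity_types, schema$relation_types, "O")
  head <- softmax_train(ds$X, ds$y, labels, epochs = config$epochs,
                        lr = config$lr, momentum = config$momentum,
                        l2 = config$l2, seed = config$seed,
                        class_weight_alpha = config$class_weight_alpha)
  structure(list(encoder = encoder, head = head, config = config,
                 schema = schema),
            class = "span_tagger")
}

#' @export
print.span_tagger <- function(x, ...) {
  cat("<span_tagger>\n  "); print(x$head)
  invisible(x)
}

#' One-row training summary of a fitted span tagger
#' @param x A fitted model object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.span_tagger <- function(x, ...) {
  tibble(n_labels = length(x$head$labels),
         epochs = length(x$head$loss_log),
         final_loss = utils::tail(x$head$loss_log, 1L),
         seed = x$config$seed)
}

#' Tidy the training loss log of a fitted head
#' @param x A fitted `span_tagger` (or relation/factuality) model.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`.
#' @export
tidy.span_tagger <- function(x, ...) {
  tibble(epoch = seq_along(x$head$loss_log), loss = x$head$loss_log)
}

# ---- decoding ---------------------------------------------------------------

#' Decode scored spans into a mention set
#'
#' Argmax decoding over per-span label distributions with ties resolved
#' toward null.  Overlapping and nested non-null spans are all kept by
#' default; an optional non-nesting filter retains only the best span in
#' each group of nested same-decision spans.
#'
#' @param P Matrix of span label probabilities (columns named by label).
#' @param spans Tibble of the corresponding candidate spans.
#' @param non_nesting If `TRUE`, drop spans strictly contained in a
#'   higher-scoring non-null span.  Default `FALSE` (nesting allowed).
#' @return `spans` filtered to non-null decisions, with columns `label`
#'   and `score`.
#' @export
decode_spans <- function(P, spans, non_nesting = FALSE) {
  lab <- argmax_with_null_ties(P)
  score <- P[cbind(seq_len(nrow(P)), match(lab, colnames(P)))]
  out <- spans
  out$label <- lab
  out$score <- score
  out <- out[out$label != "O", , drop = FALSE]
  if (non_nesting && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$score)
    for (i in ord) {
      if (!keep[i]) next
      inside <- out$start >= out$start[i] & out$end <= out$end[i] &
        !(out$start == out$start[i] & out$end == out$end[i])
      keep[inside & keep & out$score < out$score[i]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Predict entity and trigger mentions for a document
#'
#' Every candidate span whose argmax label is non-null is emitted; spans
#' labelled with an entity type become entities, spans labelled with a
#' relation type become triggers.  Nested and overlapping outputs are
#' permitted.
#'
#' @param model A fitted `span_tagger`.
#' @param doc A [standoff_document()].
#' @return A list with elements `entities` and `triggers` (mention
#'   tibbles with character-offset fragments) and `doc` (the document
#'   with predictions attached).
#' @export
predict_mentions <- function(model, doc) {
  schema <- model$schema
  cfg <- model$config
  if (is.null(doc$sentences)) doc <- segment_sentences(doc)
  ents <- list(); trgs <- list()
  views <- doc_sentence_views(doc)
  for (view in views) {
    n <- nrow(view$tokens)
    if (n == 0L) next
    cands <- enumerate_spans(n, cfg$max_span_length)
    packs <- pack_neighborhood(view$tokens$token, cands, cfg$cap)
    off <- 0L
    reps <- list()
    for (pk in packs) {
      enc <- encode_pack(model$encoder, pk)
      reps[[length(reps) + 1L]] <-
        span_features(lev_representations(enc, pk), model$encoder$width)
    }
    R <- do.call(rbind, reps)
    P <- softmax_predict(model$head, R)
    dec <- decode_spans(P, cands)
    for (i in seq_len(nrow(dec))) {
      cs <- view$tokens$start[dec$start[i] + 1L]
      ce <- view$tokens$end[dec$end[i] + 1L]
      frag <- span_location(cs, ce)
      row <- tibble(id = NA_character_, type = dec$label[i],
                    fragments = list(frag),
                    surface = slice_surface(doc$text, frag),
                    score = dec$score[i], sentence = view$sentence)
      if (dec$label[i] %in% schema$entity_types) {
        ents[[length(ents) + 1L]] <- row
      } else {
        trgs[[length(trgs) + 1L]] <- row
      }
    }
  }
  entities <- if (length(ents)) dplyr::bind_rows(ents) else
    dplyr::mutate(empty_mentions(), score = numeric(), sentence = integer())
  triggers <- if (length(trgs)) dplyr::bind_rows(trgs) else
    dplyr::mutate(empty_mentions(), score = numeric(), sentence = integer())
  if (nrow(entities)) entities$id <- paste0("T", seq_len(nrow(entities)))
  if (nrow(triggers)) triggers$id <- paste0("T", nrow(entities) + seq_len(nrow(triggers)))
  pred_doc <- standoff_document(doc$doc_id, doc$text, doc$section,
                                entities = entities[, c("id", "type", "fragments", "surface")],
                                triggers = triggers[, c("id", "type", "fragments", "surface")],
                                sentences = doc$sentences)
  list(entities = entities, triggers = triggers, doc = pred_doc)
}
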