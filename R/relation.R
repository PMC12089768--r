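# Relation classification (span-pair and subject-trigger-oriented
# triples), factuality classification, and pipeline orchestration.

#' Enumerate relation candidates in one sentence
#'
#' @param entities Token-span tibble (`id`, `type`, `start`, `end`) of the
#'   sentence's entity mentions.
#' @param triggers Same for trigger mentions.
#' @param mode `"pairs"` (all ordered entity pairs) or `"triples"` (all
#'   subject/trigger/object combinations).
#' @return A tibble with columns `subject_id`, `object_id`, `trigger_id`
#'   (NA in pair mode), in deterministic order.
#' @export
generate_candidates <- function(entities, triggers = NULL,
                                mode = c("pairs", "triples")) {
  mode <- match.arg(mode)
  out <- tibble(subject_id = character(), object_id = character(),
                trigger_id = character())
  if (nrow(entities) < 2L) return(out)
  entities <- dplyr::arrange(entities, .data$start, .data$end)
  pairs <- tidyr::expand_grid(subject_id = entities$id, object_id = entities$id)
  pairs <- pairs[pairs$subject_id != pairs$object_id, ]
  if (mode == "pairs") {
    pairs$trigger_id <- NA_character_
    return(pairs)
  }
  if (is.null(triggers) || nrow(triggers) == 0L) return(out)
  triggers <- dplyr::arrange(triggers, .data$start, .data$end)
  out <- tidyr::expand_grid(subject_id = entities$id,
                            trigger_id = triggers$id,
                            object_id = entities$id)
  out <- out[out$subject_id != out$object_id, ]
  out[, c("subject_id", "object_id", "trigger_id")]
}

# Gold label of an ordered (subject, object) pair given the document's
# relations: directional relations label the (agent, theme) order;
# symmetric relations label both orders.  Returns "O" when unrelated.
gold_pair_label <- function(relations, subject_id, object_id,
                            schema = default_schema()) {
  for (i in seq_len(nrow(relations))) {
    r <- relations[i, ]
    if (relation_signature(r$type, schema) == "directional") {
      if (!is.na(r$agent) && r$agent == subject_id &&
          !is.na(r$theme1) && r$theme1 == object_id) return(r$type)
    } else {
      th <- c(r$theme1, r$theme2)
      if (all(c(subject_id, object_id) %in% th)) return(r$type)
    }
  }
  "O"
}

gold_pair_relation_index <- function(relations, subject_id, object_id,
                                     schema = default_schema()) {
  for (i in seq_len(nrow(relations))) {
    r <- relations[i, ]
    if (relation_signature(r$type, schema) == "directional") {
      if (!is.na(r$agent) && r$agent == subject_id &&
          !is.na(r$theme1) && r$theme1 == object_id) return(i)
    } else {
      th <- c(r$theme1, r$theme2)
      if (all(c(subject_id, object_id) %in% th)) return(i)
    }
  }
  NA_integer_
}

# ---- representations --------------------------------------------------------

# Span-pair representations for one sentence view: one subject-oriented
# pack per subject, objects carried as levitated pairs.  Returns a tibble
# (subject_id, object_id) and a matrix of features (4 x encoder width).
pair_representations <- function(encoder, view, cap = 30L) {
  ents <- dplyr::arrange(view$entities, .data$start, .data$end)
  n <- nrow(ents)
  if (n < 2L) return(list(index = tibble(subject_id = character(),
                                         object_id = character()),
                          X = NULL))
  sid <- character(); oid <- character(); feats <- list()
  for (s in seq_len(n)) {
    objs <- ents[-s, ]
    packs <- pack_subject_oriented(view$tokens$token, ents[s, ], objs, cap)
    done <- 0L
    for (pk in packs) {
      enc <- encode_pack(encoder, pk)
      w <- encoder$width
      srep <- span_features(matrix(solid_representation(enc, pk, "subj"), 1L), w)
      OR <- span_features(lev_representations(enc, pk), w)
      k <- nrow(OR)
      sid <- c(sid, rep(ents$id[s], k))
      oid <- c(oid, objs$id[done + seq_len(k)])
      feats[[length(feats) + 1L]] <-
        cbind(matrix(srep, k, length(srep), byrow = TRUE), OR)
      done <- done + k
    }
  }
  list(index = tibble(subject_id = sid, object_id = oid),
       X = do.call(rbind, feats))
}

# Triple representations: subject and trigger solid-marked, objects
# levitated; features are 6 x encoder width.
triple_representations <- function(encoder, view, cap = 30L) {
  ents <- dplyr::arrange(view$entities, .data$start, .data$end)
  trgs <- dplyr::arrange(view$triggers, .data$start, .data$end)
  empty <- list(index = tibble(subject_id = character(),
                               object_id = character(),
                               trigger_id = character()), X = NULL)
  if (nrow(ents) < 2L || nrow(trgs) < 1L) return(empty)
  frames <- make_triple_frames(ents, trgs)
  sid <- character(); oid <- character(); tid <- character(); feats <- list()
  for (fr in frames) {
    packs <- pack_subject_trigger(view$tokens$token, list(fr), cap)
    done <- 0L
    for (pk in packs) {
      enc <- encode_pack(encoder, pk)
      w <- encoder$width
      srep <- span_features(matrix(solid_representation(enc, pk, "subj"), 1L), w)
      trep <- span_features(matrix(solid_representation(enc, pk, "trg"), 1L), w)
      OR <- span_features(lev_representations(enc, pk), w)
      k <- nrow(OR)
      sid <- c(sid, rep(fr$subject$id, k))
      oid <- c(oid, fr$objects$id[done + seq_len(k)])
      tid <- c(tid, rep(fr$trigger$id, k))
      feats[[length(feats) + 1L]] <-
        cbind(matrix(c(srep, trep), k, 2L * length(srep), byrow = TRUE), OR)
      done <- done + k
    }
  }
  list(index = tibble(subject_id = sid, object_id = oid, trigger_id = tid),
       X = do.call(rbind, feats))
}

# ---- training ---------------------------------------------------------------

#' Train the relation classifier
#'
#' Classifies ordered (subject, object) pairs — or (subject, trigger,
#' object) triples when `use_triggers = TRUE` — into the 13 relation
#' types plus null, by cross-entropy.  All non-gold ordered pairs in a
#' sentence are null training instances; symmetric types are trained in
#' both orders.  In triple mode a triple is positive only when the gold
#' relation between subject and object is anchored on that trigger.
#'
#' @param corpus Gold training corpus (segmented; cross-sentence
#'   relations are excluded automatically).
#' @param encoder A [frozen_encoder()].
#' @param config A [train_config()].
#' @param use_triggers Train on subject-trigger-oriented triples.
#' @param schema An [default_schema()] object.
#' @return A `relation_model`.
#' @export
train_relation_classifier <- function(corpus, encoder,
                                      config = train_config(),
                                      use_triggers = FALSE,
                                      schema = default_schema()) {
  X <- list(); y <- list()
  for (doc in corpus) {
    if (!doc$section %in% config$sections) next
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    doc <- filter_sentence_bound(doc, drop = TRUE)
    views <- doc_sentence_views(doc)
    rel_sent <- relation_sentences(doc)
    for (si in seq_along(views)) {
      view <- views[[si]]
      rels <- doc$relations[!is.na(rel_sent) & rel_sent == si, ]
      rp <- if (use_triggers) triple_representations(encoder, view, config$cap)
            else pair_representations(encoder, view, config$cap)
      if (is.null(rp$X)) next
      lab <- character(nrow(rp$index))
      for (i in seq_len(nrow(rp$index))) {
        k <- gold_pair_relation_index(rels, rp$index$subject_id[i],
                                      rp$index$object_id[i], schema)
        if (is.na(k)) { lab[i] <- "O"; next }
        if (use_triggers) {
          gt <- rels$trigger[k]
          lab[i] <- if (!is.na(gt) && gt == rp$index$trigger_id[i])
            rels$type[k] else "O"
        } else lab[i] <- rels$type[k]
      }
      X[[length(X) + 1L]] <- rp$X
      y[[length(y) + 1L]] <- lab
    }
  }
  if (length(X) == 0L) stop("no relation training instances", call. = FALSE)
  Xm <- do.call(rbind, X); yv <- unlist(y)
  if (!any(yv != "O")) stop("no positive relation examples", call. = FALSE)
  labels <- c(schema$relation_types, "O")
  head <- softmax_train(Xm, yv, labels, epochs = config$epochs, lr = config$lr,
                        momentum = config$momentum, l2 = config$l2,
                        seed = config$seed,
                        class_weight_alpha = config$class_weight_alpha)
  structure(list(encoder = encoder, head = head, config = config,
                 schema = schema, use_triggers = use_triggers,
                 null_fraction = mean(yv == "O")),
            class = "relation_model")
}

#' @export
print.relation_model <- function(x, ...) {
  cat(sprintf("<relation_model (%s), null fraction %.2f>\n  ",
              if (x$use_triggers) "subject-trigger triples" else "span pairs",
              x$null_fraction))
  print(x$head)
  invisible(x)
}

# Sentence index of each relation (all members in one sentence, else NA).
relation_sentences <- function(doc) {
  if (nrow(doc$relations) == 0L) return(integer())
  lookup <- c(
    stats::setNames(mention_sentence_index(doc, doc$entities), doc$entities$id),
    stats::setNames(mention_sentence_index(doc, doc$triggers), doc$triggers$id)
  )
  vapply(seq_len(nrow(doc$relations)), function(i) {
    r <- doc$relations[i, ]
    mm <- c(r$agent, r$theme1, r$theme2, r$trigger)
    mm <- mm[!is.na(mm)]
    s <- unique(lookup[mm])
    if (length(s) == 1L && !anyNA(s)) s else NA_integer_
  }, integer(1L))
}

# ---- prediction -------------------------------------------------------------

#' Predict typed relations over a set of mentions
#'
#' Pair mode classifies every ordered entity pair in a sentence.  Triple
#' mode enumerates triples over the available triggers and accepts a pair
#' if any triple over it classifies non-null (keeping the best-scoring
#' type); sentences with no trigger fall back to the pair-mode model when
#' one is supplied.  Duplicate predictions are merged keeping the maximum
#' score; symmetric types are reported with the earlier span first.
#'
#' @param model A `relation_model`.
#' @param entities,triggers Predicted (or gold) mention tibbles with
#'   `id`, `type`, `fragments`.
#' @param doc The source [standoff_document()] (for text and sentences).
#' @param fallback Optional pair-mode `relation_model` used for
#'   trigger-less sentences when `model` is a triple model.
#' @return Tibble of typed relation predictions: `subject_id`,
#'   `object_id`, `trigger_id`, `type`, `score`, `sentence`.
#' @export
predict_relations <- function(model, entities, triggers, doc,
                              fallback = NULL) {
  schema <- model$schema
  carrier <- standoff_document(doc$doc_id, doc$text, doc$section,
                               entities = entities[, c("id", "type", "fragments", "surface")],
                               triggers = triggers[, c("id", "type", "fragments", "surface")],
                               sentences = doc$sentences)
  if (is.null(carrier$sentences)) carrier <- segment_sentences(carrier)
  views <- doc_sentence_views(carrier)
  preds <- list()
  for (view in views) {
    use_triples <- model$use_triggers && nrow(view$triggers) > 0L
    mdl <- if (model$use_triggers && !use_triples) fallback else model
    if (is.null(mdl)) next
    rp <- if (use_triples) triple_representations(mdl$encoder, view, mdl$config$cap)
          else pair_representations(mdl$encoder, view, mdl$config$cap)
    if (is.null(rp$X)) next
    P <- softmax_predict(mdl$head, rp$X)
    lab <- argmax_with_null_ties(P)
    score <- P[cbind(seq_len(nrow(P)), match(lab, colnames(P)))]
    keep <- lab != "O"
    if (!any(keep)) next
    tb <- rp$index[keep, , drop = FALSE]
    if (!"trigger_id" %in% names(tb)) tb$trigger_id <- NA_character_
    tb$type <- lab[keep]
    tb$score <- score[keep]
    tb$sentence <- view$sentence
    preds[[length(preds) + 1L]] <- tb
  }
  out <- dplyr::bind_rows(preds)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(subject_id = character(), object_id = character(),
                  trigger_id = character(), type = character(),
                  score = numeric(), sentence = integer()))
  }
  merge_relation_predictions(out, entities, schema)
}

# Canonicalize symmetric predictions (earlier span first) and merge
# duplicates keeping the maximum score.
merge_relation_predictions <- function(preds, entities, schema) {
  starts <- stats::setNames(
    vapply(entities$fragments, function(f) span_envelope(f)[1L], integer(1L)),
    entities$id)
  sym <- relation_signature(preds$type, schema) == "symmetric"
  flip <- sym & starts[preds$subject_id] > starts[preds$object_id]
  tmp <- preds$subject_id[flip]
  preds$subject_id[flip] <- preds$object_id[flip]
  preds$object_id[flip] <- tmp
  preds %>%
    group_by(.data$type, .data$subject_id, .data$object_id) %>%
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) %>%
    ungroup() %>%
    arrange(.data$sentence, .data$subject_id, .data$object_id)
}

# ---- factuality -------------------------------------------------------------

#' Train the factuality (certainty) classifier
#'
#' Three-way classification over {Factual, Negated, Uncertain} on the
#' same span-pair representation as relation classification, trained on
#' the gold relations' coarsened certainty levels.  A class missing from
#' the training data is kept in the label space with a warning.
#'
#' @inheritParams train_relation_classifier
#' @param l2 Ridge penalty for the factuality head.  Stronger than the
#'   span/relation default: certainty hinges on a handful of cue-word
#'   directions in the context channel, and heavier shrinkage steers the
#'   head toward those shared directions instead of per-instance span
#'   idiosyncrasies.
#' @return A `factuality_model`.
#' @export
train_factuality_classifier <- function(corpus, encoder,
                                        config = train_config(),
                                        schema = default_schema(),
                                        l2 = 1e-3) {
  X <- list(); y <- list()
  for (doc in corpus) {
    if (!doc$section %in% config$sections) next
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    doc <- filter_sentence_bound(doc, drop = TRUE)
    views <- doc_sentence_views(doc)
    rel_sent <- relation_sentences(doc)
    for (si in seq_along(views)) {
      view <- views[[si]]
      rels <- doc$relations[!is.na(rel_sent) & rel_sent == si, ]
      if (nrow(rels) == 0L) next
      rp <- pair_representations(encoder, view, config$cap)
      if (is.null(rp$X)) next
      for (i in seq_len(nrow(rels))) {
        r <- rels[i, ]
        subj <- if (!is.na(r$agent)) r$agent else r$theme1
        obj <- if (!is.na(r$agent)) r$theme1 else r$theme2
        hit <- which(rp$index$subject_id == subj & rp$index$object_id == obj)
        if (length(hit) == 0L) next
        X[[length(X) + 1L]] <- rp$X[hit[1L], , drop = FALSE]
        y[[length(y) + 1L]] <- map_certainty(r$certainty, schema)
      }
    }
  }
  if (length(X) == 0L) stop("no factuality training instances", call. = FALSE)
  Xm <- do.call(rbind, X); yv <- unlist(y)
  labels <- schema$certainty_coarse
  missing <- setdiff(labels, unique(yv))
  if (length(missing)) {
    warning("certainty class(es) absent from training data: ",
            paste(missing, collapse = ", "), " (kept in label space)",
            call. = FALSE)
  }
  head <- softmax_train(Xm, yv, labels, epochs = config$epochs, lr = config$lr,
                        momentum = config$momentum, l2 = l2,
                        seed = config$seed,
                        class_weight_alpha = config$class_weight_alpha)
  structure(list(encoder = encoder, head = head, config = config,
                 schema = schema),
            class = "factuality_model")
}

#' @export
print.factuality_model <- function(x, ...) {
  cat("<factuality_model>\n  "); print(x$head)
  invisible(x)
}

# Predict a coarse certainty for each predicted relation.
predict_factuality <- function(model, relations, entities, doc) {
  if (nrow(relations) == 0L) {
    relations$certainty <- character()
    return(relations)
  }
  carrier <- standoff_document(doc$doc_id, doc$text, doc$section,
                               entities = entities[, c("id", "type", "fragments", "surface")],
                               sentences = doc$sentences)
  views <- doc_sentence_views(carrier)
  relations$certainty <- NA_character_
  for (si in unique(relations$sentence)) {
    view <- views[[si]]
    rp <- pair_representations(model$encoder, view, model$config$cap)
    if (is.null(rp$X)) next
    ix <- which(relations$sentence == si)
    for (i in ix) {
      hit <- which(rp$index$subject_id == relations$subject_id[i] &
                     rp$index$object_id == relations$object_id[i])
      if (length(hit) == 0L) next
      P <- softmax_predict(model$head, rp$X[hit[1L], , drop = FALSE])
      relations$certainty[i] <- colnames(P)[which.max(P)]
    }
  }
  relations$certainty[is.na(relations$certainty)] <- "Factual"
  relations
}

# ---- pipeline ---------------------------------------------------------------

#' Run the three-stage extraction pipeline
#'
#' Chains (1) entity and trigger recognition, (2) relation extraction and
#' (3) factuality detection on predicted upstream outputs.  Gold-entity
#' and gold-trigger injection modes are available for ablations.
#'
#' @param docs List of gold [standoff_document()]s (used for text; gold
#'   annotations are only consulted in the injection modes).
#' @param models List with elements `tagger` (a `span_tagger`),
#'   `relation` (pair-mode `relation_model`), optional `relation_triple`
#'   (triple-mode model) and `factuality`.
#' @param gold_entities,gold_triggers Inject gold mentions instead of
#'   predictions.
#' @param use_triggers Use the triple-mode relation model (with pair-mode
#'   fallback for trigger-less sentences).
#' @return List of predicted [standoff_document()]s (one per input
#'   document), with predicted certainty stored on each relation.
#' @export
run_pipeline <- function(docs, models, gold_entities = FALSE,
                         gold_triggers = FALSE, use_triggers = FALSE) {
  if (is.null(models$tagger) && !(gold_entities && (gold_triggers || !use_triggers))) {
    stop("pipeline needs a tagger model unless gold mentions are injected",
         call. = FALSE)
  }
  if (use_triggers && is.null(models$relation_triple)) {
    stop("use_triggers = TRUE needs models$relation_triple", call. = FALSE)
  }
  if (!use_triggers && is.null(models$relation)) {
    stop("pipeline needs models$relation", call. = FALSE)
  }
  if (is.null(models$factuality)) stop("pipeline needs models$factuality",
                                       call. = FALSE)
  schema <- models$factuality$schema
  lapply(docs, function(doc) {
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    need_pred <- !(gold_entities && (gold_triggers || !use_triggers))
    pm <- if (need_pred) predict_mentions(models$tagger, doc) else NULL
    entities <- if (gold_entities) doc$entities else
      pm$entities[, c("id", "type", "fragments", "surface")]
    triggers <- if (gold_triggers) doc$triggers else if (!is.null(pm))
      pm$triggers[, c("id", "type", "fragments", "surface")] else empty_mentions()
    rel_model <- if (use_triggers) models$relation_triple else models$relation
    rels <- predict_relations(rel_model, entities, triggers, doc,
                              fallback = models$relation)
    rels <- predict_factuality(models$factuality, rels, entities, doc)
    rel_tb <- relation_tibble_from_predictions(rels, schema)
    standoff_document(doc$doc_id, doc$text, doc$section,
                      entities = entities, triggers = triggers,
                      relations = rel_tb, sentences = doc$sentences)
  })
}

relation_tibble_from_predictions <- function(preds, schema) {
  if (nrow(preds) == 0L) return(empty_relations())
  n <- nrow(preds)
  sym <- relation_signature(preds$type, schema) == "symmetric"
  tibble(
    id = paste0("R", seq_len(n)),
    type = preds$type,
    agent = ifelse(sym, NA_character_, preds$subject_id),
    theme1 = ifelse(sym, preds$subject_id, preds$object_id),
    theme2 = ifelse(sym, preds$object_id, NA_character_),
    trigger = if ("trigger_id" %in% names(preds)) preds$trigger_id else NA_character_,
    certainty = preds$certainty,
    sentence_bound = TRUE
  )
}
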