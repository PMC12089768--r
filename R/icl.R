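# Zero- and one-shot relation + certainty extraction over gold entities
# through a provider-agnostic chat-completion interface: a model is any
# function `complete(prompt) -> text`.  Prompts carry a task
# description, a guideline over the admissible relation types, an
# optional retrieved demonstration, and a test sample with the two gold
# entities wrapped in markers, followed by three multiple-choice
# questions (relation yes/no; relation type from a filtered choice set;
# certainty level).

#' Build the relation-type choice set for an entity-type pair
#'
#' Candidate relation types offered in the prompt are filtered to those
#' occurring at least `min_count` times between the two entity types in
#' the training corpus (in subject-to-object order for directional
#' types; either order for symmetric ones).
#'
#' @param train_corpus List of gold [standoff_document()]s.
#' @param subject_type,object_type Entity type names.
#' @param min_count Minimum support (default 3).
#' @param schema An [default_schema()] object.
#' @return Sorted character vector of relation types (possibly empty).
#' @export
build_choice_set <- function(train_corpus, subject_type, object_type,
                             min_count = 3L, schema = default_schema()) {
  counts <- pair_type_counts(train_corpus, schema)
  hit <- counts$n[counts$subject_type == subject_type &
                    counts$object_type == object_type]
  sel <- counts[counts$subject_type == subject_type &
                  counts$object_type == object_type &
                  counts$n >= min_count, ]
  sort(unique(sel$type))
}

# Count relation types by (subject entity type, object entity type).
pair_type_counts <- function(corpus, schema = default_schema()) {
  rows <- list()
  for (doc in corpus) {
    if (nrow(doc$relations) == 0L) next
    ty <- stats::setNames(doc$entities$type, doc$entities$id)
    for (i in seq_len(nrow(doc$relations))) {
      r <- doc$relations[i, ]
      if (relation_signature(r$type, schema) == "directional") {
        if (is.na(r$agent) || is.na(r$theme1)) next
        rows[[length(rows) + 1L]] <- tibble(
          subject_type = unname(ty[r$agent]), object_type = unname(ty[r$theme1]),
          type = r$type)
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          subject_type = unname(ty[c(r$theme1, r$theme2)]),
          object_type = unname(ty[c(r$theme2, r$theme1)]),
          type = r$type)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(subject_type = character(), object_type = character(),
                  type = character(), n = integer()))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::count(.data$subject_type, .data$object_type, .data$type)
}

#' Retrieve the most similar training demonstrations
#'
#' kNN retrieval by cosine similarity between sentence embeddings, with
#' deterministic tie-breaks by pool index.  The default embedding is the
#' mean of frozen token embeddings (see [frozen_encoder()]); any
#' function mapping a character vector to an embedding matrix may be
#' supplied.
#'
#' @param pool Character vector of training sentences.
#' @param query A single test sentence.
#' @param k Number of demonstrations (default 1).
#' @param embed Embedding function `character -> matrix` (rows =
#'   sentences).
#' @return Integer indices into `pool`, best first; empty when the pool
#'   is empty (zero-shot fallback).
#' @export
retrieve_demonstration <- function(pool, query, k = 1L,
                                   embed = default_sentence_embedding) {
  if (length(pool) == 0L) return(integer())
  E <- embed(c(query, pool))
  q <- E[1L, ]
  P <- E[-1L, , drop = FALSE]
  sims <- as.numeric(P %*% q) /
    (sqrt(rowSums(P^2)) * sqrt(sum(q^2)) + 1e-12)
  ord <- order(-sims, seq_along(pool))
  utils::head(ord, k)
}

#' Default sentence embedding (mean of frozen token embeddings)
#' @param sentences Character vector.
#' @param encoder A [frozen_encoder()].
#' @return Numeric matrix, one row per sentence.
#' @export
default_sentence_embedding <- function(sentences, encoder = frozen_encoder()) {
  t(vapply(sentences, function(s) {
    toks <- tokenize_words(s)$token
    if (length(toks) == 0L) return(numeric(encoder$dim))
    colMeans(do.call(rbind, lapply(toks, function(tk)
      token_embedding(encoder, tk))))
  }, numeric(encoder$dim)))
}

# ---- prompting --------------------------------------------------------------

# Insert [E1]..[/E1] / [E2]..[/E2] markers around the two gold mentions
# by character offsets (robust to repeated surfaces).
mark_sentence <- function(text, frag1, frag2) {
  e1 <- span_envelope(frag1); e2 <- span_envelope(frag2)
  ins <- dplyr::arrange(tibble(
    pos = c(e1[1L], e1[2L], e2[1L], e2[2L]),
    tag = c("[E1] ", " [/E1]", "[E2] ", " [/E2]"),
    open = c(TRUE, FALSE, TRUE, FALSE)
  ), dplyr::desc(.data$pos), .data$open)
  out <- text
  for (i in seq_len(nrow(ins))) {
    out <- paste0(substring(out, 1L, ins$pos[i]), ins$tag[i],
                  substring(out, ins$pos[i] + 1L))
  }
  out
}

#' Build a relation-extraction prompt
#'
#' Deterministic rendering of the prompt: task description, guideline
#' over the admissible relation types, optional demonstration block
#' (omitted in zero-shot mode), and the test sample with marked
#' entities, followed by the three multiple-choice questions.
#'
#' @param spec A list with elements `choice_set` (non-empty character
#'   vector), `sentence` (marked test sentence), `subject_surface`,
#'   `object_surface`, optional `demonstration` (list with `sentence`,
#'   `answer`), and `certainty_levels`.
#' @return A single prompt string.
#' @export
build_prompt <- function(spec) {
  stopifnot(length(spec$choice_set) > 0L)
  letters_ <- LETTERS[seq_along(spec$choice_set)]
  guide <- paste(sprintf("  %s. %s", letters_, spec$choice_set), collapse = "\n")
  demo <- ""
  if (!is.null(spec$demonstration)) {
    demo <- paste0(
      "### Demonstration\nSentence: ", spec$demonstration$sentence,
      "\nAnswers: ", spec$demonstration$answer, "\n\n")
  }
  certs <- spec$certainty_levels %||% c("Factual", "Negated", "Uncertain")
  paste0(
    "### Task\n",
    "Decide whether a relation holds between the two marked entities, ",
    "its type, and the certainty the authors assign to it.\n\n",
    "### Guideline\nAdmissible relation types for this entity pair:\n",
    guide, "\n\n", demo,
    "### Test sample\nSentence: ", spec$sentence, "\n",
    "Entity 1 (subject): ", spec$subject_surface, "\n",
    "Entity 2 (object): ", spec$object_surface, "\n\n",
    "Q1. Is there a relation? (Relation / No relation)\n",
    "Q2. If so, which type? ",
    paste(sprintf("%s: %s", letters_, spec$choice_set), collapse = ", "), "\n",
    "Q3. Certainty? ", paste(certs, collapse = " / "), "\n",
    "Answer with the format: 1: <Relation|No relation>, 2: <letter>, 3: <certainty>\n"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a chat-completion answer into a structured prediction
#'
#' Maps lettered or named choices back to schema labels.  Unparseable
#' completions and answers outside the choice set yield "no relation"
#' with `parse_failure = TRUE`; parsing is total.
#'
#' @param raw Raw completion text.
#' @param choice_set The relation types that were offered.
#' @return A list: `has_relation`, `type` (or `NA`), `certainty` (or
#'   `NA`), `parse_failure`.
#' @export
parse_response <- function(raw, choice_set) {
  no_rel <- list(has_relation = FALSE, type = NA_character_,
                 certainty = NA_character_, parse_failure = FALSE)
  if (is.null(raw) || !nzchar(trimws(raw %||% ""))) {
    no_rel$parse_failure <- TRUE
    return(no_rel)
  }
  if (grepl("no\\s+relation", raw, ignore.case = TRUE)) return(no_rel)
  # Q2: letter or explicit type name
  type <- NA_character_
  m <- regmatches(raw, regexpr("2\\s*:\\s*([A-Z])\\b", raw))
  if (length(m) && nzchar(m)) {
    letter <- sub("2\\s*:\\s*", "", m)
    ix <- match(letter, LETTERS[seq_along(choice_set)])
    if (!is.na(ix)) type <- choice_set[ix]
  }
  if (is.na(type)) {
    for (ct in choice_set) {
      if (grepl(paste0("\\b", ct, "\\b"), raw)) { type <- ct; break }
    }
  }
  if (is.na(type)) {
    no_rel$parse_failure <- TRUE
    return(no_rel)
  }
  cert <- NA_character_
  for (cl in c("Factual", "Negated", "Uncertain")) {
    if (grepl(cl, raw, ignore.case = TRUE)) { cert <- cl; break }
  }
  if (is.na(cert)) cert <- "Factual"
  list(has_relation = TRUE, type = type, certainty = cert,
       parse_failure = FALSE)
}

# ---- harness ----------------------------------------------------------------

#' Run zero-/one-shot relation extraction over gold entities
#'
#' For every ordered gold entity pair inside a sentence whose entity-type
#' choice set is non-empty, builds a prompt, queries the model, and
#' parses the answer.  Demonstrations (one-shot mode) are retrieved from
#' the training corpus by sentence-embedding similarity.  Predicted
#' documents reuse the gold entity mentions, so downstream scoring
#' isolates relation and certainty quality.
#'
#' @param test_corpus,train_corpus Lists of gold [standoff_document()]s.
#' @param complete Chat-completion function `prompt -> text`.
#' @param shots 0 (zero-shot) or 1 (one-shot with retrieval).
#' @param subset Fraction of test documents to process (document-level
#'   subsample; e.g. 0.1).
#' @param seed Seed for the subsample.
#' @param min_count Choice-set support threshold.
#' @param restrict_to_gold_pairs Only prompt for pairs that hold a gold
#'   relation (the "known-relation" evaluation variant).
#' @param schema An [default_schema()] object.
#' @return A list: `pred_docs`, `gold_docs` (the processed subset),
#'   `log` (tibble of per-pair outcomes incl. parse failures and skipped
#'   pairs).
#' @export
run_icl <- function(test_corpus, train_corpus, complete, shots = 0L,
                    subset = 1.0, seed = 1L, min_count = 3L,
                    restrict_to_gold_pairs = FALSE,
                    schema = default_schema()) {
  stopifnot(shots %in% c(0L, 1L))
  old <- .Random.seed_get()
  set.seed(seed)
  n_take <- max(1L, round(subset * length(test_corpus)))
  take <- sort(sample.int(length(test_corpus), n_take))
  .Random.seed_set(old)
  gold_docs <- test_corpus[take]

  counts <- pair_type_counts(train_corpus, schema)
  # demonstration pool: one entry per gold relation sentence
  pool <- icl_demo_pool(train_corpus, schema)
  log_rows <- list()
  pred_docs <- lapply(gold_docs, function(doc) {
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    views <- doc_sentence_views(doc)
    ty <- stats::setNames(doc$entities$type, doc$entities$id)
    frag <- stats::setNames(doc$entities$fragments, doc$entities$id)
    surf <- stats::setNames(doc$entities$surface, doc$entities$id)
    preds <- list()
    for (view in views) {
      cands <- generate_candidates(view$entities, mode = "pairs")
      if (restrict_to_gold_pairs && nrow(cands) > 0L) {
        keep <- vapply(seq_len(nrow(cands)), function(i) {
          gold_pair_label(doc$relations, cands$subject_id[i],
                          cands$object_id[i], schema) != "O"
        }, logical(1L))
        cands <- cands[keep, , drop = FALSE]
      }
      s0 <- doc$sentences$start[view$sentence]
      s1 <- doc$sentences$end[view$sentence]
      sent_text <- substring(doc$text, s0 + 1L, s1)
      for (i in seq_len(nrow(cands))) {
        sid <- cands$subject_id[i]; oid <- cands$object_id[i]
        cs <- build_choice_set(train_corpus, ty[[sid]], ty[[oid]],
                               min_count, schema)
        if (length(cs) == 0L) {
          log_rows[[length(log_rows) + 1L]] <<- tibble(
            doc_id = doc$doc_id, subject_id = sid, object_id = oid,
            outcome = "skipped_empty_choice_set", parse_failure = FALSE)
          next
        }
        marked <- mark_sentence(trimws(sent_text),
                                frag[[sid]] - s0 - (s0 > 0L),
                                frag[[oid]] - s0 - (s0 > 0L))
        demo <- NULL
        if (shots == 1L && nrow(pool) > 0L) {
          ix <- retrieve_demonstration(pool$sentence, sent_text, k = 1L)
          if (length(ix)) demo <- list(sentence = pool$sentence[ix],
                                       answer = pool$answer[ix])
        }
        prompt <- build_prompt(list(
          choice_set = cs, sentence = marked,
          subject_surface = surf[[sid]], object_surface = surf[[oid]],
          demonstration = demo))
        ans <- parse_response(complete(prompt), cs)
        log_rows[[length(log_rows) + 1L]] <<- tibble(
          doc_id = doc$doc_id, subject_id = sid, object_id = oid,
          outcome = if (ans$has_relation) "relation" else "no_relation",
          parse_failure = ans$parse_failure)
        if (ans$has_relation) {
          preds[[length(preds) + 1L]] <- tibble(
            subject_id = sid, object_id = oid, trigger_id = NA_character_,
            type = ans$type, score = 1, sentence = view$sentence,
            certainty = ans$certainty)
        }
      }
    }
    pred <- dplyr::bind_rows(preds)
    rel_tb <- if (!is.null(pred) && nrow(pred)) {
      merged <- merge_relation_predictions(pred, doc$entities, schema)
      tb <- relation_tibble_from_predictions(merged, schema)
      tb$certainty <- merged$certainty
      tb
    } else empty_relations()
    standoff_document(doc$doc_id, doc$text, doc$section,
                      entities = doc$entities, triggers = empty_mentions(),
                      relations = rel_tb, sentences = doc$sentences)
  })
  list(pred_docs = pred_docs, gold_docs = gold_docs,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
         tibble(doc_id = character(), subject_id = character(),
                object_id = character(), outcome = character(),
                parse_failure = logical()))
}

# Demonstration pool: gold relation sentences with rendered answers.
icl_demo_pool <- function(corpus, schema = default_schema()) {
  rows <- list()
  for (doc in corpus) {
    if (nrow(doc$relations) == 0L) next
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    rs <- relation_sentences(doc)
    for (i in seq_len(nrow(doc$relations))) {
      if (is.na(rs[i])) next
      r <- doc$relations[i, ]
      s0 <- doc$sentences$start[rs[i]]; s1 <- doc$sentences$end[rs[i]]
      rows[[length(rows) + 1L]] <- tibble(
        sentence = trimws(substring(doc$text, s0 + 1L, s1)),
        answer = sprintf("1: Relation, 2: %s, 3: %s", r$type,
                         map_certainty(r$certainty, schema)))
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(sentence = character(), answer = character())
}

#' Score an in-context-learning run
#'
#' Delegates to [score_task()]: relation extraction and end-to-end (with
#' certainty) reports on the processed subset, plus the parse-failure
#' rate.
#'
#' @param run Result of [run_icl()].
#' @param mode Matching mode.
#' @param schema An [default_schema()] object.
#' @return A list: `relation` and `end2end` `eval_report`s,
#'   `parse_failure_rate`.
#' @export
evaluate_icl <- function(run, mode = "strict", schema = default_schema()) {
  gold <- lapply(run$gold_docs, function(d) {
    if (is.null(d$sentences)) d <- segment_sentences(d)
    filter_sentence_bound(d, drop = TRUE)
  })
  list(
    relation = score_task(gold, run$pred_docs, "relation", mode, schema = schema),
    end2end = score_task(gold, run$pred_docs, "end2end", mode, schema = schema),
    parse_failure_rate = if (nrow(run$log)) mean(run$log$parse_failure) else 0
  )
}

#' An oracle chat model answering from gold annotations
#'
#' Builds a `complete(prompt) -> text` function that looks up the gold
#' relation for the marked entity pair in the prompt's test sample and
#' answers it in the expected format; unrelated pairs get "No relation".
#' Useful for verifying the harness plumbing end to end (the harness
#' must score F1 = 1 against such a model).
#'
#' @param corpus Gold corpus the oracle may consult.
#' @param schema An [default_schema()] object.
#' @return A function `prompt -> text`.
#' @export
oracle_chat_model <- function(corpus, schema = default_schema()) {
  keys <- new.env(parent = emptyenv())
  for (doc in corpus) {
    if (is.null(doc$sentences)) doc <- segment_sentences(doc)
    surf <- stats::setNames(doc$entities$surface, doc$entities$id)
    rs <- relation_sentences(doc)
    for (i in seq_len(nrow(doc$relations))) {
      if (is.na(rs[i])) next
      r <- doc$relations[i, ]
      cert <- map_certainty(r$certainty, schema)
      s0 <- doc$sentences$start[rs[i]]; s1 <- doc$sentences$end[rs[i]]
      sent <- trimws(substring(doc$text, s0 + 1L, s1))
      store <- function(s, o) {
        keys[[paste(sent, s, o, sep = "\r")]] <-
          list(type = r$type, certainty = cert)
      }
      if (relation_signature(r$type, schema) == "directional") {
        if (!is.na(r$agent) && !is.na(r$theme1))
          store(surf[[r$agent]], surf[[r$theme1]])
      } else {
        store(surf[[r$theme1]], surf[[r$theme2]])
        store(surf[[r$theme2]], surf[[r$theme1]])
      }
    }
  }
  function(prompt) {
    subj <- sub(".*Entity 1 \\(subject\\): ([^\n]*)\n.*", "\\1", prompt)
    obj <- sub(".*Entity 2 \\(object\\): ([^\n]*)\n.*", "\\1", prompt)
    marked <- sub(".*Test sample\nSentence: ([^\n]*)\n.*", "\\1", prompt)
    sent <- gsub("\\[E[12]\\] | \\[/E[12]\\]", "", marked)
    hit <- keys[[paste(sent, subj, obj, sep = "\r")]]
    if (is.null(hit)) return("1: No relation")
    sprintf("1: Relation, 2: %s, 3: %s", hit$type, hit$certainty)
  }
}
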