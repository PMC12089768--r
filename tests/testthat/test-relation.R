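test_that("candidate generation counts ordered pairs and triples", {
  ents <- tibble::tibble(id = c("T1", "T2", "T3"), type = "Food",
                         start = c(0L, 2L, 4L), end = c(0L, 2L, 4L))
  trgs <- tibble::tibble(id = "T9", type = "increases", start = 1L, end = 1L)
  expect_identical(nrow(generate_candidates(ents, mode = "pairs")), 6L)
  expect_identical(nrow(generate_candidates(ents, trgs, mode = "triples")), 6L)
  expect_identical(nrow(generate_candidates(ents[1, ], mode = "pairs")), 0L)
  expect_identical(nrow(generate_candidates(ents, trgs[0, ], mode = "triples")), 0L)
})

test_that("the relation classifier memorizes its training corpus", {
  ms <- small_models()
  gold <- lapply(ms$corpus, function(d)
    filter_sentence_bound(segment_sentences(d), drop = TRUE))
  pred <- run_pipeline(ms$corpus,
                       list(tagger = ms$tagger, relation = ms$relation,
                            factuality = ms$factuality),
                       gold_entities = TRUE)
  f1 <- glance(score_task(gold, pred, "relation", "strict"))$f1
  expect_gte(f1, 0.95)
})

test_that("null candidates dominate when all pairs are enumerated", {
  expect_gte(small_models()$relation$null_fraction, 0.6)
})

test_that("factuality cues drive certainty predictions on memorized data", {
  ms <- small_models()
  gold <- lapply(ms$corpus, function(d)
    filter_sentence_bound(segment_sentences(d), drop = TRUE))
  pred <- run_pipeline(ms$corpus,
                       list(tagger = ms$tagger, relation = ms$relation,
                            factuality = ms$factuality),
                       gold_entities = TRUE)
  # collect per-relation certainty agreement against gold
  joined <- list()
  for (k in seq_along(gold)) {
    gd <- gold[[k]]; pd <- pred[[k]]
    m <- nutriminer:::match_relations(gd, pd, "strict")
    for (j in which(m$pred_status == "tp")) {
      joined[[length(joined) + 1L]] <- data.frame(
        gold = map_certainty(gd$relations$certainty[m$pred_gold_ix[j]]),
        pred = pd$relations$certainty[j])
    }
  }
  joined <- do.call(rbind, joined)
  neg <- joined[joined$gold == "Negated", ]
  unc <- joined[joined$gold == "Uncertain", ]
  expect_gt(nrow(neg), 0L)
  expect_gt(nrow(unc), 0L)
  expect_gte(mean(neg$pred == "Negated"), 0.9)
  expect_gte(mean(unc$pred == "Uncertain"), 0.9)
})

test_that("a corpus with only Factual labels predicts Factual everywhere", {
  gen <- cached("factual_gen", generate_corpus(generator_config(
    n_docs = 6, seed = 3,
    certainty_probs = c(Factual = 1, Negated = 0, Unknown = 0,
                        Possible = 0, Probable = 0, Doubtful = 0))))
  enc <- frozen_encoder(dim = 16, seed = 2)
  expect_warning(
    fm <- train_factuality_classifier(gen$corpus, enc,
                                      train_config(epochs = 50, seed = 2)),
    "absent from training data")
  expect_setequal(fm$head$labels, c("Factual", "Negated", "Uncertain"))
  ms <- list(tagger = NULL, relation = small_models()$relation,
             factuality = fm)
  pred <- run_pipeline(gen$corpus, ms, gold_entities = TRUE)
  certs <- unlist(lapply(pred, function(d) d$relations$certainty))
  expect_true(all(certs == "Factual"))
})

test_that("the pipeline validates its model inputs", {
  ms <- small_models()
  expect_error(run_pipeline(small_gen()$corpus, list(tagger = ms$tagger)),
               "relation")
  expect_error(run_pipeline(small_gen()$corpus,
                            list(tagger = ms$tagger, relation = ms$relation)),
               "factuality")
  expect_error(run_pipeline(small_gen()$corpus,
                            list(tagger = ms$tagger, factuality = ms$factuality),
                            use_triggers = TRUE),
               "relation_triple")
  expect_identical(run_pipeline(list(), list(tagger = ms$tagger,
                                             relation = ms$relation,
                                             factuality = ms$factuality)),
                   list())
})

test_that("end-to-end scores never exceed relation scores", {
  ms <- small_models()
  test_docs <- medium_gen()$corpus[1:12]
  gold <- lapply(test_docs, function(d)
    filter_sentence_bound(segment_sentences(d), drop = TRUE))
  for (goldmode in c(FALSE, TRUE)) {
    pred <- run_pipeline(test_docs,
                         list(tagger = ms$tagger, relation = ms$relation,
                              factuality = ms$factuality),
                         gold_entities = goldmode)
    for (mode in c("strict", "relaxed")) {
      re <- glance(score_task(gold, pred, "relation", mode))$f1
      e2e <- glance(score_task(gold, pred, "end2end", mode))$f1
      expect_lte(e2e, re + 1e-12)
      expect_lte(glance(score_task(gold, pred, "relation", "strict"))$f1,
                 glance(score_task(gold, pred, "relation", "relaxed"))$f1 + 1e-12)
    }
  }
})

test_that("predicting twice merges to the same relation set", {
  ms <- small_models()
  doc <- segment_sentences(small_gen()$corpus[[3L]])
  p1 <- predict_relations(ms$relation, doc$entities, doc$triggers, doc)
  p2 <- predict_relations(ms$relation, doc$entities, doc$triggers, doc)
  expect_equal(p1, p2)
  merged_again <- nutriminer:::merge_relation_predictions(
    dplyr::bind_rows(p1, p1), doc$entities, default_schema())
  expect_identical(nrow(merged_again), nrow(p1))
})

test_that("symmetric predictions are canonicalized with the earlier span first", {
  ents <- small_gen()$corpus[[1L]]$entities
  preds <- tibble::tibble(
    subject_id = c(ents$id[2L], ents$id[1L]),
    object_id = c(ents$id[1L], ents$id[2L]),
    trigger_id = NA_character_,
    type = "associated_with", score = c(0.4, 0.9), sentence = 1L)
  out <- nutriminer:::merge_relation_predictions(preds, ents, default_schema())
  expect_identical(nrow(out), 1L)
  starts <- vapply(ents$fragments[1:2], function(f) min(f[, 1L]), integer(1L))
  expect_identical(out$subject_id, ents$id[1:2][which.min(starts)])
  expect_equal(out$score, 0.9)
})
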