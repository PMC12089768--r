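# Shared fixtures and independent oracles for the test suite.  Expensive
# objects (generated corpora, trained models) are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A hand-written 3-line standoff fixture with a discontinuous mention.
fixture_disc <- function() {
  txt <- "fecal overall starch decreased butyrate."
  ann <- paste(
    "T1\tNutrient 0 5;14 20\tfecal starch",
    "T2\tMetabolite 31 39\tbutyrate",
    "T3\tdecreases 21 30\tdecreased",
    "E1\tdecreases:T3 Agent:T1 Theme:T2",
    sep = "\n")
  list(txt = txt, ann = ann)
}

# The nested-mention fixture: inner Nutrient inside an outer Food phrase.
fixture_nested <- function() {
  txt <- "PC-enriched virgin olive oil decreased blood ox-ldl in adults."
  ann <- paste(
    "T1\tNutrient 0 2\tPC",
    "T2\tFood 0 28\tPC-enriched virgin olive oil",
    "T3\tMeasurement 39 51\tblood ox-ldl",
    "T4\tPopulation 55 61\tadults",
    "T5\tdecreases 29 38\tdecreased",
    "E1\tdecreases:T5 Agent:T2 Theme:T3",
    "A1\tFactuality E1 Factual",
    sep = "\n")
  list(txt = txt, ann = ann)
}

small_gen <- function() cached("small_gen", generate_corpus(
  generator_config(n_docs = 7, sentences_per_doc = 3, seed = 11)))

medium_gen <- function() cached("medium_gen", generate_corpus(
  generator_config(n_docs = 40, sentences_per_doc = 3, seed = 23)))

# A small trained model bundle (shared by pipeline/eval property tests).
small_models <- function() cached("small_models", {
  corpus <- small_gen()$corpus
  enc <- frozen_encoder(dim = 32, seed = 5)
  cfg <- train_config(epochs = 200, seed = 13)
  list(
    encoder = enc, config = cfg, corpus = corpus,
    tagger = train_span_tagger(corpus, enc, cfg),
    relation = train_relation_classifier(corpus, enc, cfg),
    relation_triple = train_relation_classifier(corpus, enc, cfg,
                                                use_triggers = TRUE),
    factuality = train_factuality_classifier(corpus, enc, cfg)
  )
})

# Brute-force maximum bipartite matching oracle: largest one-to-one
# matching between gold and predicted mentions under a compatibility
# predicate, found by exhaustive recursion.  Independent of the greedy
# matcher under test.
oracle_max_matching <- function(gold, pred, mode) {
  compat <- function(i, j) {
    if (gold$type[i] != pred$type[j]) return(FALSE)
    if (mode == "strict") {
      fa <- gold$fragments[[i]]; fb <- pred$fragments[[j]]
      return(nrow(fa) == nrow(fb) && all(fa == fb))
    }
    ea <- range(gold$fragments[[i]]); eb <- range(pred$fragments[[j]])
    min(ea[2], eb[2]) - max(ea[1], eb[1]) > 0
  }
  ng <- nrow(gold); np <- nrow(pred)
  best <- 0L
  recurse <- function(i, used_p, count) {
    if (i > ng) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used_p, count) # leave gold i unmatched
    for (j in seq_len(np)) {
      if (!used_p[j] && compat(i, j)) {
        used_p[j] <- TRUE
        recurse(i + 1L, used_p, count + 1L)
        used_p[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, np), 0L)
  best
}

# Random small mention sets over a shared document text, for matcher
# oracle equivalence tests.
random_mentions <- function(n, seed, types = c("Food", "Nutrient")) {
  set.seed(seed)
  k <- sample.int(n, 1L)
  rows <- lapply(seq_len(k), function(i) {
    s <- sample.int(40L, 1L) - 1L
    w <- sample.int(6L, 1L)
    frag <- span_location(s, s + w)
    tibble::tibble(id = paste0("M", i), type = sample(types, 1L),
                   fragments = list(frag), surface = "x")
  })
  dplyr::bind_rows(rows)
}

make_doc_with <- function(doc_id, entities = NULL, triggers = NULL,
                          relations = NULL, text = strrep("x", 60)) {
  standoff_document(doc_id, text,
                    entities = entities %||% nutriminer:::empty_mentions(),
                    triggers = triggers %||% nutriminer:::empty_mentions(),
                    relations = relations %||% nutriminer:::empty_relations())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
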