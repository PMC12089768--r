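test_that("a single sentence without a terminator spans all text", {
  doc <- segment_sentences(standoff_document("d", "no terminator here"))
  expect_identical(doc$sentences$start, 0L)
  expect_identical(doc$sentences$end, 18L)
})

test_that("two sentences split after the terminator with offsets preserved", {
  txt <- "Participants ate fiber. Bifidobacterium increased."
  doc <- segment_sentences(standoff_document("d", txt))
  expect_identical(nrow(doc$sentences), 2L)
  expect_identical(doc$sentences$start, c(0L, 23L))
  expect_identical(doc$sentences$end, c(23L, nchar(txt)))
  # boundaries partition the text
  expect_identical(doc$sentences$end[1L], doc$sentences$start[2L])
})

test_that("genus initials and abbreviations do not end sentences", {
  txt <- "B. longum grew, e.g. in feces. Counts rose."
  doc <- segment_sentences(standoff_document("d", txt))
  expect_identical(nrow(doc$sentences), 2L)
  expect_identical(doc$sentences$start[2L], 30L)
})

test_that("a boundary that would split a mention is moved past it", {
  txt <- "We measured pH. Then more."
  ents <- tibble::tibble(id = "T1", type = "Measurement",
                         fragments = list(span_location(12L, 20L)),
                         surface = "pH. Then")
  doc <- segment_sentences(make_doc_with("d", entities = ents, text = txt))
  inner <- doc$sentences$end[-nrow(doc$sentences)]
  expect_true(all(inner <= 12L | inner >= 20L))
})

test_that("generated corpora segment exactly as the ledger records", {
  gen <- small_gen()
  for (doc in gen$corpus) {
    reseg <- segment_sentences(standoff_document(
      doc$doc_id, doc$text, doc$section, entities = doc$entities,
      triggers = doc$triggers, relations = doc$relations))
    expect_equal(as.data.frame(reseg$sentences),
                 as.data.frame(gen$ledger$sentence_boundaries[[doc$doc_id]]))
  }
})

test_that("sentence-bound filtering keeps in-sentence relations only", {
  txt <- "inulin increased butyrate. pectin decreased glycemia."
  ents <- dplyr::bind_rows(
    tibble::tibble(id = "T1", type = "Nutrient", fragments = list(span_location(0L, 6L)), surface = "inulin"),
    tibble::tibble(id = "T2", type = "Metabolite", fragments = list(span_location(17L, 25L)), surface = "butyrate"),
    tibble::tibble(id = "T3", type = "Nutrient", fragments = list(span_location(27L, 33L)), surface = "pectin"),
    tibble::tibble(id = "T4", type = "Measurement", fragments = list(span_location(44L, 52L)), surface = "glycemia"))
  rel <- nutriminer:::empty_relations()
  rel[1L, ] <- list("R1", "increases", "T1", "T2", NA, NA, "Factual", NA)
  rel[2L, ] <- list("R2", "associated_with", NA, "T2", "T3", NA, "Unknown", NA)
  doc <- segment_sentences(make_doc_with("d", entities = ents,
                                         relations = rel, text = txt))
  flagged <- filter_sentence_bound(doc, drop = FALSE)
  expect_identical(flagged$relations$sentence_bound, c(TRUE, FALSE))
  dropped <- filter_sentence_bound(doc, drop = TRUE)
  expect_identical(dropped$relations$id, "R1")
  expect_identical(nrow(dropped$entities), 4L) # entities untouched
})

test_that("cross-sentence exclusion matches the generator ledger exactly", {
  gen <- medium_gen()
  n_cross <- sum(vapply(gen$corpus, function(d) {
    d2 <- filter_sentence_bound(d, drop = FALSE)
    sum(!d2$relations$sentence_bound)
  }, integer(1L)))
  expect_identical(n_cross, gen$ledger$n_cross_sentence)
})

test_that("corpus statistics equal the generator ledger", {
  gen <- medium_gen()
  st <- corpus_statistics(gen$corpus)
  led <- gen$ledger
  tot <- st$totals[st$totals$section == "total", ]
  expect_identical(tot$documents, led$n_docs)
  expect_identical(tot$sentences_total, led$n_sentences)
  expect_identical(tot$entities_total, led$n_entities)
  expect_identical(tot$triggers_total, led$n_triggers)
  expect_identical(tot$relations_total, led$n_relations)
  expect_identical(st$entity_types$n,
                   as.integer(led$entity_type_counts[st$entity_types$type]))
  expect_identical(st$relation_types$n_relations,
                   as.integer(led$relation_type_counts[st$relation_types$type]))
  expect_identical(st$certainty$n,
                   as.integer(led$certainty_counts[st$certainty$level]))
  rates <- st$rates
  expect_identical(rates$n[rates$measure == "nested_mentions"], led$n_nested)
  expect_identical(rates$n[rates$measure == "discontinuous_mentions"],
                   led$n_discontinuous)
  expect_identical(rates$n[rates$measure == "cross_sentence_relations"],
                   led$n_cross_sentence)
  # per-type counts sum to totals; shares sum to 100
  expect_identical(sum(st$entity_types$n), led$n_entities)
  expect_equal(sum(st$entity_types$share_pct), 100)
  expect_equal(sum(st$relation_types$share_pct), 100)
})

test_that("an empty corpus yields all-zero statistics", {
  st <- corpus_statistics(list())
  tot <- st$totals[st$totals$section == "total", ]
  expect_identical(tot$entities_total, 0L)
  expect_identical(tot$relations_total, 0L)
  expect_identical(sum(st$entity_types$n), 0L)
})

test_that("title/abstract and results section counts add to totals", {
  gen <- cached("split_gen", generate_corpus(
    generator_config(n_docs = 12, n_results_docs = 4, seed = 31)))
  st <- corpus_statistics(gen$corpus)
  tot <- st$totals
  for (col in c("documents", "sentences_total", "entities_total",
                "triggers_total", "relations_total")) {
    expect_identical(
      tot[[col]][tot$section == "title_abstract"] +
        tot[[col]][tot$section == "results"],
      tot[[col]][tot$section == "total"])
  }
})
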