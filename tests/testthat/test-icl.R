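icl_corpus <- function() cached("icl_corpus", {
  gen <- generate_corpus(generator_config(n_docs = 30, seed = 57))
  lapply(gen$corpus, function(d)
    filter_sentence_bound(segment_sentences(d), drop = TRUE))
})

test_that("choice sets honour the support threshold", {
  # constructed corpus: (Nutrient, Microorganism) hosts increases x5,
  # decreases x2
  mk <- function(doc_id, type) {
    ents <- dplyr::bind_rows(
      tibble::tibble(id = "T1", type = "Nutrient",
                     fragments = list(span_location(0L, 6L)), surface = "inulin"),
      tibble::tibble(id = "T2", type = "Microorganism",
                     fragments = list(span_location(17L, 26L)), surface = "Roseburia"))
    rel <- nutriminer:::empty_relations()
    rel[1L, ] <- list("R1", type, "T1", "T2", NA, NA, "Factual", NA)
    make_doc_with(doc_id, entities = ents, relations = rel,
                  text = "inulin increased Roseburia.")
  }
  corpus <- c(lapply(1:5, function(i) mk(paste0("i", i), "increases")),
              lapply(1:2, function(i) mk(paste0("d", i), "decreases")))
  expect_identical(build_choice_set(corpus, "Nutrient", "Microorganism"),
                   "increases")
  expect_setequal(build_choice_set(corpus, "Nutrient", "Microorganism",
                                   min_count = 1L),
                  c("increases", "decreases"))
  expect_identical(build_choice_set(corpus, "Gene", "Disease"), character())
})

test_that("retrieval ranks by cosine similarity with deterministic ties", {
  # orthogonal embedding fixture: brute-force ranking oracle
  emb <- function(sentences) {
    basis <- diag(4L)
    t(vapply(sentences, function(s) {
      i <- as.integer(sub("s", "", strsplit(s, " ")[[1L]][1L]))
      basis[i, ] + 0.01 * as.integer(sub("s", "", strsplit(s, " ")[[1L]][2L]))
    }, numeric(4L)))
  }
  pool <- c("s1 s1", "s2 s1", "s1 s2", "s3 s1")
  got <- retrieve_demonstration(pool, "s1 s0", k = 4L, embed = emb)
  E <- emb(c("s1 s0", pool))
  sims <- as.numeric(E[-1, ] %*% E[1, ]) /
    (sqrt(rowSums(E[-1, ]^2)) * sqrt(sum(E[1, ]^2)))
  expect_identical(got, order(-sims, seq_along(pool)))

  # a sentence present verbatim retrieves itself; k > pool returns all
  pool2 <- c("inulin increased butyrate.", "pectin decreased glycemia.")
  self <- retrieve_demonstration(pool2, "pectin decreased glycemia.", k = 1L)
  expect_identical(self, 2L)
  expect_length(retrieve_demonstration(pool2, "anything", k = 10L), 2L)
  expect_length(retrieve_demonstration(character(), "x"), 0L)
})

test_that("prompts render deterministically with and without demonstrations", {
  spec <- list(choice_set = c("decreases", "increases"),
               sentence = "[E1] inulin [/E1] increased [E2] butyrate [/E2].",
               subject_surface = "inulin", object_surface = "butyrate")
  p0 <- build_prompt(spec)
  expect_false(grepl("Demonstration", p0))
  expect_identical(p0, build_prompt(spec))
  spec$demonstration <- list(sentence = "pectin decreased glycemia.",
                             answer = "1: Relation, 2: A, 3: Factual")
  p1 <- build_prompt(spec)
  expect_true(grepl("Demonstration", p1))
  expect_lt(regexpr("Demonstration", p1), regexpr("Test sample", p1))
  expect_error(build_prompt(list(choice_set = character())))
})

test_that("entity markers wrap exactly the mention surfaces", {
  txt <- "inulin increased inulin uptake."
  m <- nutriminer:::mark_sentence(txt, span_location(0L, 6L),
                                  span_location(17L, 23L))
  expect_identical(m, "[E1] inulin [/E1] increased [E2] inulin [/E2] uptake.")
})

test_that("answer parsing is total and maps choices back to labels", {
  cs <- c("decreases", "increases", "pos_associated_with")
  good <- parse_response("1: Relation, 2: B, 3: Factual", cs)
  expect_true(good$has_relation)
  expect_identical(good$type, "increases")
  expect_identical(good$certainty, "Factual")
  expect_false(good$parse_failure)

  none <- parse_response("1: No relation", cs)
  expect_false(none$has_relation)
  expect_false(none$parse_failure)

  empty <- parse_response("", cs)
  expect_false(empty$has_relation)
  expect_true(empty$parse_failure)

  named <- parse_response("2: pos_associated_with, 3: Uncertain", cs)
  expect_identical(named$type, "pos_associated_with")

  # answers outside the offered choice set fail closed
  outside <- parse_response("1: Relation, 2: worsens, 3: Factual", cs)
  expect_false(outside$has_relation)
  expect_true(outside$parse_failure)
  garbled <- parse_response("the quick brown fox", cs)
  expect_false(garbled$has_relation)
  expect_true(garbled$parse_failure)
})

test_that("a mocked oracle model achieves perfect harness scores", {
  corpus <- icl_corpus()
  test_docs <- corpus[1:8]
  model <- oracle_chat_model(test_docs)
  # choice sets built over the same documents so every gold pair type is
  # offered; this isolates harness plumbing from train/test type overlap
  run <- run_icl(test_docs, test_docs, model, shots = 0L, min_count = 1L)
  ev <- evaluate_icl(run)
  expect_equal(glance(ev$relation)$f1, 1)
  expect_equal(glance(ev$end2end)$f1, 1)
  expect_equal(ev$parse_failure_rate, 0)
})

test_that("one-shot mode retrieves a demonstration into the prompt", {
  corpus <- icl_corpus()
  seen <- new.env(); seen$demo <- FALSE
  spy <- function(prompt) {
    if (grepl("Demonstration", prompt)) seen$demo <- TRUE
    "1: No relation"
  }
  run_icl(corpus[1:2], corpus[3:20], spy, shots = 1L, min_count = 1L)
  expect_true(seen$demo)
})

test_that("the subset fraction is an exact, seeded document subsample", {
  corpus <- icl_corpus()
  nul <- function(prompt) "1: No relation"
  r1 <- run_icl(corpus, corpus, nul, subset = 0.1, seed = 3L, min_count = 1L)
  r2 <- run_icl(corpus, corpus, nul, subset = 0.1, seed = 3L, min_count = 1L)
  expect_identical(length(r1$gold_docs), 3L)
  expect_identical(names(r1$gold_docs), names(r2$gold_docs))
})

test_that("restriction to known-relation pairs changes only the prompted set", {
  corpus <- icl_corpus()
  count_env <- new.env(); count_env$n <- 0L
  counting_oracle <- local({
    inner <- oracle_chat_model(corpus[1:4])
    function(prompt) { count_env$n <- count_env$n + 1L; inner(prompt) }
  })
  full <- run_icl(corpus[1:4], corpus[1:4], counting_oracle, min_count = 1L)
  n_full <- count_env$n
  count_env$n <- 0L
  restr <- run_icl(corpus[1:4], corpus[1:4], counting_oracle, min_count = 1L,
                   restrict_to_gold_pairs = TRUE)
  expect_lt(count_env$n, n_full)
  expect_equal(glance(evaluate_icl(restr)$relation)$f1, 1)
})

test_that("pairs with empty choice sets are skipped and recorded", {
  corpus <- icl_corpus()
  nul <- function(prompt) "1: No relation"
  run <- run_icl(corpus[1:3], corpus[4:6], nul, min_count = 1000L)
  expect_true(all(run$log$outcome == "skipped_empty_choice_set"))
  expect_identical(sum(vapply(run$pred_docs, function(d)
    nrow(d$relations), integer(1L))), 0L)
})
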