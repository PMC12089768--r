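mention <- function(id, type, s, e, surface = "x") {
  tibble::tibble(id = id, type = type,
                 fragments = list(span_location(s, e)), surface = surface)
}

test_that("identical mention sets match perfectly in both modes", {
  g <- dplyr::bind_rows(mention("T1", "Food", 0, 4), mention("T2", "Disease", 9, 15))
  for (mode in c("strict", "relaxed")) {
    m <- match_mentions(g, g, mode)
    expect_identical(nrow(m$tp), 2L)
    expect_length(m$fp, 0L)
    expect_length(m$fn, 0L)
  }
})

test_that("a boundary shift is a strict miss but a relaxed hit", {
  g <- mention("T1", "Food", 5, 12)
  p <- mention("P1", "Food", 7, 14)
  strict <- match_mentions(g, p, "strict")
  expect_identical(nrow(strict$tp), 0L)
  expect_identical(strict$fp, 1L)
  expect_identical(strict$fn, 1L)
  relaxed <- match_mentions(g, p, "relaxed")
  expect_identical(nrow(relaxed$tp), 1L)
  # type must match even with overlap
  p2 <- mention("P1", "Disease", 7, 14)
  expect_identical(nrow(match_mentions(g, p2, "relaxed")$tp), 0L)
})

test_that("greedy matching equals the exhaustive bipartite oracle", {
  for (seed in 1:40) {
    g <- random_mentions(5L, seed)
    p <- random_mentions(5L, seed + 1000L)
    for (mode in c("strict", "relaxed")) {
      got <- nrow(match_mentions(g, p, mode)$tp)
      expect_identical(got, oracle_max_matching(g, p, mode),
                       info = sprintf("seed %d mode %s", seed, mode))
    }
  }
})

test_that("micro F1 on a 3-document fixture equals the hand-computed value", {
  gold <- list(
    make_doc_with("d1", entities = dplyr::bind_rows(
      mention("T1", "Food", 0, 4), mention("T2", "Disease", 10, 14))),
    make_doc_with("d2", entities = mention("T1", "Nutrient", 0, 6)),
    make_doc_with("d3", entities = mention("T1", "Gene", 3, 7))
  )
  pred <- list(
    make_doc_with("d1", entities = dplyr::bind_rows(
      mention("P1", "Food", 0, 4), mention("P2", "Disease", 20, 24))),
    make_doc_with("d2", entities = dplyr::bind_rows(
      mention("P1", "Nutrient", 0, 6), mention("P2", "Enzyme", 10, 12))),
    make_doc_with("d3", entities = mention("P1", "Gene", 3, 7))
  )
  rep <- score_task(gold, pred, "ner", "strict")
  # pooled: TP = 3 (Food d1, Nutrient d2, Gene d3), FP = 2, FN = 1
  expect_identical(rep$micro$tp, 3L)
  expect_identical(rep$micro$fp, 2L)
  expect_identical(rep$micro$fn, 1L)
  p <- 3 / 5; r <- 3 / 4
  expect_equal(rep$micro$f1, 2 * p * r / (p + r), tolerance = 1e-9)
  # recomputing micro F1 from pooled per-class counts agrees
  pc <- rep$per_class
  expect_identical(sum(pc$tp), rep$micro$tp)
  expect_identical(sum(pc$fp), rep$micro$fp)
  expect_identical(sum(pc$fn), rep$micro$fn)
})

rel_doc <- function(doc_id, rel_type = "increases", certainty = "Factual",
                    flip_dir = FALSE, with_rel = TRUE) {
  ents <- dplyr::bind_rows(mention("T1", "Nutrient", 0, 6),
                           mention("T2", "Metabolite", 17, 25))
  rel <- nutriminer:::empty_relations()
  if (with_rel) {
    if (flip_dir) {
      rel[1L, ] <- list("R1", rel_type, "T2", "T1", NA, NA, certainty, NA)
    } else {
      rel[1L, ] <- list("R1", rel_type, "T1", "T2", NA, NA, certainty, NA)
    }
  }
  make_doc_with(doc_id, entities = ents, relations = rel,
                text = "inulin increased butyrate.")
}

test_that("perfect relation predictions score 1 with and without certainty", {
  gold <- list(rel_doc("d1"), rel_doc("d2", certainty = "Negated"))
  for (mode in c("strict", "relaxed")) {
    expect_equal(glance(score_task(gold, gold, "relation", mode))$f1, 1)
    expect_equal(glance(score_task(gold, gold, "end2end", mode))$f1, 1)
  }
})

test_that("a correct relation with wrong certainty fails only end-to-end", {
  gold <- list(rel_doc("d1", certainty = "Factual"))
  pred <- list(rel_doc("d1", certainty = "Negated"))
  expect_equal(glance(score_task(gold, pred, "relation", "strict"))$f1, 1)
  e2e <- score_task(gold, pred, "end2end", "strict")
  expect_identical(e2e$micro$tp, 0L)
  expect_identical(e2e$micro$fp, 1L)
  expect_identical(e2e$micro$fn, 1L)
})

test_that("direction matters for directional types, not for symmetric ones", {
  gold <- list(rel_doc("d1", "increases"))
  flipped <- list(rel_doc("d1", "increases", flip_dir = TRUE))
  expect_equal(glance(score_task(gold, flipped, "relation", "strict"))$f1, 0)
  gold_sym <- list(rel_doc("d1", "associated_with"))
  flip_sym <- list(rel_doc("d1", "associated_with", flip_dir = TRUE))
  # symmetric: theme order is immaterial (stored as agent/theme1 slots here)
  g <- gold_sym[[1L]]; f <- flip_sym[[1L]]
  g$relations$theme2 <- g$relations$theme1; g$relations$theme1 <- g$relations$agent
  g$relations$agent <- NA_character_
  f$relations$theme2 <- f$relations$theme1; f$relations$theme1 <- f$relations$agent
  f$relations$agent <- NA_character_
  expect_equal(glance(score_task(list(g), list(f), "relation", "strict"))$f1, 1)
})

test_that("factuality scoring separates its two denominator modes", {
  # two gold relations, one found (with correct certainty), one missed
  gold <- list(rel_doc("d1"), rel_doc("d2"))
  pred <- list(rel_doc("d1"), rel_doc("d2", with_rel = FALSE))
  def <- score_factuality(gold, pred)
  expect_equal(def$micro$precision, 1)
  expect_equal(def$micro$recall, 0.5)
  alt <- score_factuality(gold, pred, denominator = "matched")
  expect_equal(alt$micro$precision, 1)
  expect_equal(alt$micro$recall, 1)
  # perfect case
  perf <- score_factuality(gold, gold)
  expect_equal(perf$micro$precision, 1)
  expect_equal(perf$micro$recall, 1)
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  gold <- list(rel_doc("d1"), rel_doc("d2"), rel_doc("d3"),
               rel_doc("d4", with_rel = FALSE))
  ci1 <- bootstrap_ci(gold, gold, task = "relation", B = 200L, seed = 7L)
  ci2 <- bootstrap_ci(gold, gold, task = "relation", B = 200L, seed = 7L)
  expect_identical(ci1, ci2)
  expect_equal(ci1$lower, 1)
  expect_equal(ci1$upper, 1)
  expect_warning(ci0 <- bootstrap_ci(gold[1L], gold[1L], task = "relation",
                                     B = 50L, seed = 1L),
                 "single document")
  expect_equal(ci0$lower, ci0$upper)
})

test_that("bootstrap intervals converge with the number of replicates", {
  # 12 one-relation documents, 3 of them mispredicted, so the resampled
  # F1 genuinely varies across replicates
  gold <- lapply(sprintf("d%02d", 1:12), rel_doc)
  pred <- lapply(seq_along(gold), function(i)
    rel_doc(sprintf("d%02d", i), with_rel = i > 3))
  ci_a <- bootstrap_ci(gold, pred, task = "relation", B = 1000L, seed = 5L)
  ci_b <- bootstrap_ci(gold, pred, task = "relation", B = 2000L, seed = 11L)
  expect_gt(ci_b$upper, ci_b$lower)
  expect_lt(abs(ci_a$lower - ci_b$lower), 0.02)
  expect_lt(abs(ci_a$upper - ci_b$upper), 0.02)
  expect_lte(ci_a$lower, ci_a$estimate)
  expect_gte(ci_a$upper, ci_a$estimate)
})

test_that("IAA is symmetric and trigger matching only lowers agreement", {
  gen <- medium_gen()
  docs_a <- gen$corpus[1:10]
  # annotator B: copy of A with some boundary and certainty perturbations
  docs_b <- lapply(docs_a, function(d) {
    if (nrow(d$entities) > 2L) {
      f <- d$entities$fragments[[2L]]
      f[1L, 1L] <- max(0L, f[1L, 1L] - 1L)
      d$entities$fragments[[2L]] <- f
      d$entities$surface[2L] <- nutriminer:::slice_surface(d$text, f)
      d$entities <- d$entities[-nrow(d$entities), ]
    }
    if (nrow(d$triggers) > 1L) d$triggers <- d$triggers[-1L, ]
    d$relations <- d$relations[d$relations$theme1 %in% d$entities$id &
                                 (is.na(d$relations$trigger) |
                                    d$relations$trigger %in% d$triggers$id), ]
    d
  })
  iaa_ab <- compute_iaa(docs_a, docs_b)
  iaa_ba <- compute_iaa(docs_b, docs_a)
  expect_equal(iaa_ab$f1, iaa_ba$f1, tolerance = 1e-9)
  # partial >= exact for the same pair
  ent <- function(x, a) x$f1[x$task == "entity" & x$agreement == a]
  expect_gte(ent(iaa_ab, "partial"), ent(iaa_ab, "exact"))
  # dropping the trigger requirement never lowers relation agreement
  rel <- function(x, a, rt) x$f1[x$task == "relation" & x$agreement == a &
                                   x$require_trigger == rt]
  expect_gte(rel(iaa_ab, "exact", FALSE), rel(iaa_ab, "exact", TRUE))
  expect_gte(rel(iaa_ab, "partial", FALSE), rel(iaa_ab, "partial", TRUE))
  # identical annotations agree perfectly
  self <- compute_iaa(docs_a, docs_a)
  expect_true(all(self$f1 == 1))
})

test_that("document alignment is enforced", {
  g <- list(rel_doc("d1")); p <- list(rel_doc("dX"))
  expect_error(score_task(g, p, "ner"), "not aligned")
  expect_error(compute_iaa(g, p), "different documents")
})
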