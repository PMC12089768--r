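# Brute-force span listing, independent of enumerate_spans.
brute_spans <- function(n, L) {
  out <- NULL
  for (s in 0:(n - 1)) for (e in s:(n - 1)) {
    if (e - s + 1 <= L) out <- rbind(out, c(s, e))
  }
  out
}

test_that("span enumeration matches brute force for all small cases", {
  for (n in 1:12) for (L in 1:6) {
    sp <- enumerate_spans(n, L)
    bf <- brute_spans(n, L)
    expect_identical(nrow(sp), nrow(bf))
    expect_identical(sort(paste(sp$start, sp$end)),
                     sort(paste(bf[, 1], bf[, 2])))
  }
  # closed-form count for n >= L: n*L - L*(L-1)/2
  expect_identical(nrow(enumerate_spans(10L, 5L)), 40L)
  expect_identical(nrow(enumerate_spans(1L, 5L)), 1L)
})

test_that("spans come out ordered by start then width", {
  sp <- enumerate_spans(6L, 3L)
  expect_true(all(diff(sp$start) >= 0))
  expect_true(all(tapply(sp$width, sp$start, function(w) all(diff(w) > 0))))
})

test_that("neighborhood packing never splits a start-group under the cap", {
  toks <- letters[1:6]
  cands <- enumerate_spans(6L, 4L)
  for (cap in c(4L, 7L, 30L)) {
    packs <- pack_neighborhood(toks, cands, cap)
    seen <- character()
    for (pk in packs) {
      lev <- pk$spans$marked == "levitated"
      starts <- pk$spans$start[lev]
      expect_lte(sum(lev), cap)
      seen <- c(seen, paste(pk$spans$start[lev], pk$spans$end[lev]))
      # a start group is contained in one pack unless oversized
      for (s in unique(starts)) {
        n_here <- sum(starts == s)
        n_total <- sum(cands$start == s)
        expect_true(n_here == n_total || n_total > cap)
      }
    }
    # conservation: every candidate in exactly one pack
    expect_identical(sort(seen), sort(paste(cands$start, cands$end)))
    # total levitated markers = 2 x number of candidates
    total_marks <- sum(vapply(packs, function(pk)
      sum(pk$rows$kind %in% c("lev_start", "lev_end")), integer(1L)))
    expect_identical(total_marks, 2L * nrow(cands))
  }
})

test_that("an oversized start-group is split but others stay whole", {
  toks <- letters[1:9]
  cands <- enumerate_spans(9L, 8L)  # start 0 has 8 spans
  packs <- pack_neighborhood(toks, cands, cap = 5L)
  sizes <- vapply(packs, function(pk) sum(pk$spans$marked == "levitated"),
                  integer(1L))
  expect_true(all(sizes <= 5L))
})

test_that("a single span yields a single pack and the cap is validated", {
  packs <- pack_neighborhood(c("a", "b"), enumerate_spans(2L, 1L)[1, ])
  expect_length(packs, 1L)
  expect_error(pack_neighborhood(c("a"), enumerate_spans(1L, 1L), cap = 1L),
               "cap")
})

test_that("the visibility mask isolates levitated pairs", {
  toks <- c("w1", "w2", "w3", "w4", "w5", "w6")
  cands <- tibble::tibble(start = c(0L, 2L), end = c(1L, 4L), width = c(2L, 3L))
  pk <- pack_neighborhood(toks, cands, cap = 30L)[[1L]]
  mask <- build_visibility_mask(pk)
  rows <- pk$rows
  text_ix <- which(rows$kind == "text")
  lev_ix <- which(rows$kind %in% c("lev_start", "lev_end"))
  # text rows see exactly the text rows (equal to the no-marker mask)
  for (i in text_ix) expect_identical(which(mask[i, ]), text_ix)
  # each levitated marker sees exactly its partner and the text
  for (i in lev_ix) {
    expect_setequal(which(mask[i, ]), c(text_ix, rows$partner[i]))
    expect_false(mask[i, i])
  }
  # markers of pair A cannot see markers of pair B
  a <- which(!is.na(rows$span_id) & rows$span_id == "c1")
  b <- which(!is.na(rows$span_id) & rows$span_id == "c2")
  expect_false(any(mask[a, b]))
})

test_that("a pack with no levitated markers has full token visibility", {
  pk <- nutriminer:::new_marker_pack(c("a", "b", "c"))
  mask <- build_visibility_mask(pk)
  expect_true(all(mask))
})

test_that("marker position indices equal the span boundary token positions", {
  toks <- letters[1:5]
  pk <- pack_neighborhood(toks, tibble::tibble(start = 1L, end = 3L, width = 3L),
                          cap = 30L)[[1L]]
  rows <- pk$rows
  expect_identical(rows$position[rows$kind == "lev_start"], 1L)
  expect_identical(rows$position[rows$kind == "lev_end"], 3L)
})

test_that("subject-oriented packs insert solid markers around the subject", {
  toks <- c("inulin", "increased", "butyrate", "in", "adults")
  subject <- tibble::tibble(start = 0L, end = 0L)
  objects <- tibble::tibble(start = c(2L, 4L, 2L), end = c(2L, 4L, 3L))
  packs <- pack_subject_oriented(toks, subject, objects, cap = 2L)
  expect_length(packs, 2L)
  for (pk in packs) {
    solid <- which(pk$rows$kind == "solid")
    expect_length(solid, 2L)
    # physically inserted: solid start directly precedes the subject token
    expect_identical(pk$rows$token[solid[1L] + 1L], "inulin")
    expect_identical(pk$rows$position[solid], c(0L, 0L))
  }
  # no objects -> one pack with no levitated markers
  p0 <- pack_subject_oriented(toks, subject, NULL)
  expect_length(p0, 1L)
  expect_false(any(p0[[1L]]$rows$kind %in% c("lev_start", "lev_end")))
})

test_that("triple frames enumerate subject x trigger x object", {
  ents <- tibble::tibble(id = c("T1", "T2", "T3"), type = "Food",
                         start = c(0L, 2L, 4L), end = c(0L, 2L, 4L))
  trgs <- tibble::tibble(id = "T4", type = "increases", start = 1L, end = 1L)
  frames <- make_triple_frames(ents, trgs)
  expect_length(frames, 3L)  # one frame per subject
  n_triples <- sum(vapply(frames, function(f) nrow(f$objects), integer(1L)))
  expect_identical(n_triples, 6L)  # 3 entities, 1 trigger -> 6 triples
  expect_length(make_triple_frames(ents[1:2, ],
                                   trgs[0, , drop = FALSE]), 0L)
  packs <- pack_subject_trigger(letters[1:5], frames)
  expect_true(all(vapply(packs, function(pk)
    sum(pk$rows$kind == "solid"), integer(1L)) == 4L))
})

test_that("span representations are isolated from unrelated pairs", {
  enc <- frozen_encoder(dim = 16, seed = 3)
  toks <- c("w1", "w2", "w3", "w4", "w5", "w6")
  solo <- pack_neighborhood(toks, tibble::tibble(start = 1L, end = 2L, width = 2L))[[1L]]
  crowd <- pack_neighborhood(
    toks, tibble::tibble(start = c(1L, 0L, 3L), end = c(2L, 4L, 5L),
                         width = c(2L, 5L, 3L)))[[1L]]
  r_solo <- span_representation(encode_pack(enc, solo), solo, "c1")
  id_crowd <- crowd$spans$span_id[crowd$spans$start == 1L & crowd$spans$end == 2L]
  r_crowd <- span_representation(encode_pack(enc, crowd), crowd, id_crowd)
  expect_lt(max(abs(r_solo - r_crowd)), 1e-5)
  expect_error(span_representation(encode_pack(enc, solo), solo, "zzz"),
               "not in pack")
})

test_that("a width-1 span is flanked by both its markers", {
  pk <- pack_neighborhood(c("a", "b"), tibble::tibble(start = 1L, end = 1L,
                                                      width = 1L))[[1L]]
  rows <- pk$rows
  expect_identical(rows$position[rows$kind == "lev_start"],
                   rows$position[rows$kind == "lev_end"])
  enc <- frozen_encoder(dim = 8, seed = 1)
  rep <- span_representation(encode_pack(enc, pk), pk, "c1")
  expect_length(rep, 2L * enc$width)
})

test_that("encoding is deterministic for fixed inputs", {
  enc1 <- frozen_encoder(dim = 16, seed = 9)
  enc2 <- frozen_encoder(dim = 16, seed = 9)
  pk <- pack_neighborhood(c("inulin", "rose"), enumerate_spans(2L, 2L))[[1L]]
  expect_identical(encode_pack(enc1, pk), encode_pack(enc2, pk))
})
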