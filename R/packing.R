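# Candidate span enumeration and levitated/solid marker packing.
#
# A marker pack lays out one sentence's tokens (with solid markers
# physically inserted where required) followed by levitated marker pairs
# appended at the end of the sequence.  Marker rows share position
# indices with the first/last token of the span they mark, and a pairwise
# visibility mask restricts attention: levitated markers see their
# partner and the text; text (and solid markers) see only text and solid
# markers.  Pack internals are plain parallel vectors — they sit on the
# hot path of every training and inference call.

#' Enumerate candidate spans of a sentence
#'
#' All token spans of width at most `max_span_length`, ordered by
#' (start, width).  Token indices are 0-based and inclusive.
#'
#' @param sentence_length Number of word tokens.
#' @param max_span_length Maximum span width in tokens (default 8).
#' @return A tibble with columns `start`, `end`, `width`.
#' @export
enumerate_spans <- function(sentence_length, max_span_length = 8L) {
  stopifnot(sentence_length >= 1L, max_span_length >= 1L)
  starts <- 0L:(sentence_length - 1L)
  counts <- pmin(max_span_length, sentence_length - starts)
  start <- rep(starts, counts)
  width <- sequence(counts)
  tibble(start = start, end = start + width - 1L, width = width)
}

# span set helper: a plain list of parallel vectors
span_set <- function(span_id = character(), start = integer(),
                     end = integer(), role = character()) {
  list(span_id = as.character(span_id), start = as.integer(start),
       end = as.integer(end), role = as.character(role))
}

n_spans <- function(ss) length(ss$start)

# Build a marker pack over `tokens` (character vector); `solid` and
# `lev` are span sets with 0-based inclusive token indices.
new_marker_pack <- function(tokens, solid = span_set(), lev = span_set()) {
  n <- length(tokens)
  stopifnot(all(c(solid$end, lev$end) < n), all(c(solid$start, lev$start) >= 0L))
  token <- tokens
  position <- 0:(n - 1L)
  kind <- rep("text", n)
  span_id <- rep(NA_character_, n)
  role <- rep(NA_character_, n)
  # insert solid marker rows from the rightmost span inward
  if (n_spans(solid) > 0L) {
    for (i in order(-solid$start)) {
      s <- solid$start[i]; e <- solid$end[i]
      at_s <- which(kind == "text" & position == s)[1L]
      at_e <- which(kind == "text" & position == e)[1L]
      r <- solid$role[i]
      ins <- function(vec, at, val) append(vec, val, after = at - 1L)
      # end marker first so the start index stays valid
      token <- ins(token, at_e + 1L, paste0("</", r, ">"))
      position <- ins(position, at_e + 1L, e)
      kind <- ins(kind, at_e + 1L, "solid")
      span_id <- ins(span_id, at_e + 1L, solid$span_id[i])
      role <- ins(role, at_e + 1L, r)
      token <- ins(token, at_s, paste0("<", r, ">"))
      position <- ins(position, at_s, s)
      kind <- ins(kind, at_s, "solid")
      span_id <- ins(span_id, at_s, solid$span_id[i])
      role <- ins(role, at_s, r)
    }
  }
  partner <- rep(NA_integer_, length(token))
  nl <- n_spans(lev)
  if (nl > 0L) {
    base <- length(token)
    token <- c(token, rep(c("<lm>", "</lm>"), nl))
    position <- c(position, as.integer(rbind(lev$start, lev$end)))
    kind <- c(kind, rep(c("lev_start", "lev_end"), nl))
    span_id <- c(span_id, rep(lev$span_id, each = 2L))
    role <- c(role, rep(lev$role, each = 2L))
    pr <- base + seq_len(2L * nl)
    partner <- c(partner, as.integer(rbind(pr[c(FALSE, TRUE)], pr[c(TRUE, FALSE)])))
  }
  spans <- list(span_id = c(solid$span_id, lev$span_id),
                start = c(solid$start, lev$start),
                end = c(solid$end, lev$end),
                role = c(solid$role, lev$role),
                marked = c(rep("solid", n_spans(solid)),
                           rep("levitated", nl)))
  structure(list(rows = list(token = token, position = position, kind = kind,
                             span_id = span_id, role = role, partner = partner),
                 spans = spans, n_tokens = n),
            class = "marker_pack")
}

#' @export
print.marker_pack <- function(x, ...) {
  cat(sprintf("<marker_pack: %d tokens, %d solid spans, %d levitated pairs>\n",
              x$n_tokens, sum(x$spans$marked == "solid"),
              sum(x$spans$marked == "levitated")))
  invisible(x)
}

#' Pairwise visibility mask of a marker pack
#'
#' Directional attention: text tokens and solid markers see only text
#' tokens and solid markers (so their rows equal the mask of a pack with
#' no levitated markers); each levitated marker sees its partner and the
#' text block only.
#'
#' @param pack A marker pack.
#' @return A logical matrix; entry `[i, j]` is `TRUE` when row `i` may
#'   attend to row `j`.
#' @export
build_visibility_mask <- function(pack) {
  rows <- pack$rows
  m <- length(rows$token)
  textish <- rows$kind %in% c("text", "solid")
  mask <- matrix(FALSE, m, m)
  mask[textish, textish] <- TRUE
  lev <- which(!textish)
  for (i in lev) {
    mask[i, textish] <- TRUE
    mask[i, rows$partner[i]] <- TRUE
    mask[i, i] <- FALSE
  }
  mask
}

#' Neighborhood-oriented packing of candidate spans
#'
#' Groups spans sharing a start token, then packs adjacent start-groups
#' together so the model can compare neighbouring spans; a start-group is
#' only split when it alone exceeds the marker cap.  Every candidate
#' appears in exactly one pack, as a levitated pair.
#'
#' @param tokens Character vector of sentence tokens.
#' @param candidates Tibble from [enumerate_spans()].
#' @param cap Maximum levitated pairs per pack (default 30).
#' @return List of marker packs.
#' @export
pack_neighborhood <- function(tokens, candidates, cap = 30L) {
  if (cap < 2L) stop("marker cap must be at least 2", call. = FALSE)
  if (nrow(candidates) == 0L) return(list())
  ord <- order(candidates$start, candidates$end - candidates$start)
  candidates <- candidates[ord, ]
  groups <- split(seq_len(nrow(candidates)), candidates$start)
  batches <- list(); cur <- integer()
  for (g in groups) {
    if (length(g) > cap) { # oversized start-group: flush, then split it
      if (length(cur)) { batches[[length(batches) + 1L]] <- cur; cur <- integer() }
      for (part in split(g, ceiling(seq_along(g) / cap))) {
        batches[[length(batches) + 1L]] <- part
      }
    } else if (length(cur) + length(g) <= cap) {
      cur <- c(cur, g)
    } else {
      batches[[length(batches) + 1L]] <- cur
      cur <- g
    }
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  lapply(batches, function(ix) {
    new_marker_pack(tokens, lev = span_set(paste0("c", ix),
                                           candidates$start[ix],
                                           candidates$end[ix],
                                           rep("cand", length(ix))))
  })
}

#' Subject-oriented packing for relation classification
#'
#' The subject span is wrapped in solid markers inserted into the token
#' order; candidate object spans are carried as levitated pairs, all
#' objects for one subject kept together before splitting by the cap.
#'
#' @param tokens Sentence tokens.
#' @param subject A one-row span data frame (`start`, `end`), 0-based
#'   inclusive.
#' @param objects Span data frame of candidate objects (may be empty or
#'   `NULL`).
#' @param cap Maximum levitated pairs per pack.
#' @return List of marker packs, each containing the same solid-marked
#'   subject.
#' @export
pack_subject_oriented <- function(tokens, subject, objects, cap = 30L) {
  solid <- span_set("subj", subject$start[1L], subject$end[1L], "subj")
  nobj <- if (is.null(objects)) 0L else length(objects$start)
  if (nobj == 0L) return(list(new_marker_pack(tokens, solid = solid)))
  parts <- split(seq_len(nobj), ceiling(seq_len(nobj) / cap))
  lapply(parts, function(ix) {
    lev <- span_set(paste0("obj", ix), objects$start[ix], objects$end[ix],
                    rep("obj", length(ix)))
    new_marker_pack(tokens, solid = solid, lev = lev)
  })
}

#' Subject-trigger-oriented packing
#'
#' Extends subject-oriented packing with a solid-marked trigger span: the
#' (subject, trigger) pair acts as the key for selecting object spans,
#' each emitted unit encoding a (subject, trigger, object) triple laid
#' out as subject, trigger, then object marker groups.
#'
#' @param tokens Sentence tokens.
#' @param frames List of frames, each a list with elements `subject`,
#'   `trigger` (one-row span data frames) and `objects` (span data frame).
#' @param cap Maximum levitated pairs per pack.
#' @return List of marker packs; attribute `"frame"` gives the source
#'   frame index of each pack.
#' @export
pack_subject_trigger <- function(tokens, frames, cap = 30L) {
  packs <- list(); frame_ix <- integer()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    stopifnot(!(fr$subject$start[1L] == fr$trigger$start[1L] &&
                  fr$subject$end[1L] == fr$trigger$end[1L]))
    solid <- span_set(c("subj", "trg"),
                      c(fr$subject$start[1L], fr$trigger$start[1L]),
                      c(fr$subject$end[1L], fr$trigger$end[1L]),
                      c("subj", "trg"))
    objs <- fr$objects
    nobj <- if (is.null(objs)) 0L else length(objs$start)
    if (nobj == 0L) next
    parts <- split(seq_len(nobj), ceiling(seq_len(nobj) / cap))
    for (ix in parts) {
      lev <- span_set(paste0("obj", ix), objs$start[ix], objs$end[ix],
                      rep("obj", length(ix)))
      packs[[length(packs) + 1L]] <- new_marker_pack(tokens, solid = solid,
                                                     lev = lev)
      frame_ix <- c(frame_ix, f)
    }
  }
  attr(packs, "frame") <- frame_ix
  packs
}

#' Build the (subject, trigger, object) frames of one sentence
#'
#' With `n` entities and `t` triggers, each entity serves as subject with
#' every trigger, the remaining entities as objects: `n * t * (n - 1)`
#' triples in total (for 3 entities and 1 trigger, 6 triples).
#'
#' @param entities Span data frame of entity spans (`id`, `start`, `end`).
#' @param triggers Span data frame of trigger spans.
#' @return List of frames as consumed by [pack_subject_trigger()].
#' @export
make_triple_frames <- function(entities, triggers) {
  frames <- list()
  if (nrow(entities) < 2L || nrow(triggers) < 1L) return(frames)
  for (s in seq_len(nrow(entities))) {
    for (t in seq_len(nrow(triggers))) {
      frames[[length(frames) + 1L]] <- list(
        subject = entities[s, ], trigger = triggers[t, ],
        objects = entities[-s, ]
      )
    }
  }
  frames
}

#' Span representation from an encoded pack
#'
#' Concatenates the contextual vectors of the span's start and end
#' markers (solid or levitated, as applicable).  Because of the
#' visibility mask, a levitated span's representation depends only on the
#' text block and its own pair, not on other levitated spans in the pack.
#'
#' @param encoded Matrix of contextual vectors, one row per pack row
#'   (from [encode_pack()]).
#' @param pack The marker pack.
#' @param span_id Span identifier within the pack.
#' @return Numeric vector of length `2 * ncol(encoded)`.
#' @export
span_representation <- function(encoded, pack, span_id) {
  rows <- pack$rows
  ix <- which(!is.na(rows$span_id) & rows$span_id == span_id)
  if (length(ix) != 2L) stop("span not in pack: ", span_id, call. = FALSE)
  c(encoded[ix[1L], ], encoded[ix[2L], ])
}

# All levitated span representations of a pack at once: matrix with one
# row per levitated span (in pack order), 2*width columns.
lev_representations <- function(encoded, pack) {
  starts <- which(pack$rows$kind == "lev_start")
  ends <- which(pack$rows$kind == "lev_end")
  cbind(encoded[starts, , drop = FALSE], encoded[ends, , drop = FALSE])
}

solid_representation <- function(encoded, pack, span_id) {
  ix <- which(!is.na(pack$rows$span_id) & pack$rows$span_id == span_id &
                pack$rows$kind == "solid")
  c(encoded[ix[1L], ], encoded[ix[2L], ])
}
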