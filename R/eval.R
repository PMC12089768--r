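# Strict/relaxed scoring, factuality scoring, bootstrap confidence
# intervals, and inter-annotator agreement.

# Overlap in characters between the envelopes of two fragment lists.
envelope_overlap <- function(fa, fb) {
  ea <- span_envelope(fa); eb <- span_envelope(fb)
  max(0L, min(ea[2L], eb[2L]) - max(ea[1L], eb[1L]))
}

fragments_equal <- function(fa, fb) {
  nrow(fa) == nrow(fb) && all(fa == fb)
}

#' Match gold and predicted mentions
#'
#' One-to-one greedy matching by maximal envelope overlap with
#' deterministic tie-breaks (earlier gold span, then earlier predicted
#' span).  Strict mode requires identical fragment lists and type;
#' relaxed mode requires at least one character of envelope overlap and
#' the same type.
#'
#' @param gold,pred Mention tibbles (`id`, `type`, `fragments`).
#' @param mode `"strict"` or `"relaxed"`.
#' @return A list with `tp` (tibble of matched `gold_ix`, `pred_ix`),
#'   `fp` (unmatched pred indices) and `fn` (unmatched gold indices).
#' @export
match_mentions <- function(gold, pred, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  if (ng == 0L || np == 0L) {
    return(list(tp = fast_tibble(list(gold_ix = integer(), pred_ix = integer())),
                fp = seq_len(np), fn = seq_len(ng)))
  }
  ov <- matrix(0, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      if (gold$type[i] != pred$type[j]) next
      if (mode == "strict") {
        ov[i, j] <- if (fragments_equal(gold$fragments[[i]], pred$fragments[[j]]))
          1 else 0
      } else {
        ov[i, j] <- envelope_overlap(gold$fragments[[i]], pred$fragments[[j]])
      }
    }
  }
  gold_start <- vapply(gold$fragments, function(f) span_envelope(f)[1L], integer(1L))
  tp_g <- integer(); tp_p <- integer()
  used_g <- logical(ng); used_p <- logical(np)
  repeat {
    ov[used_g, ] <- 0; ov[, used_p] <- 0
    best <- max(ov)
    if (best <= 0) break
    cand <- which(ov == best, arr.ind = TRUE)
    # ties: earlier gold span start, then gold index, then pred index
    ord <- order(gold_start[cand[, 1L]], cand[, 1L], cand[, 2L])
    pick <- cand[ord[1L], ]
    tp_g <- c(tp_g, unname(pick[1L])); tp_p <- c(tp_p, unname(pick[2L]))
    used_g[pick[1L]] <- TRUE; used_p[pick[2L]] <- TRUE
  }
  list(tp = fast_tibble(list(gold_ix = tp_g, pred_ix = tp_p)),
       fp = which(!used_p), fn = which(!used_g))
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  fast_tibble(list(tp = tp, fp = fp, fn = fn,
                   precision = p, recall = r, f1 = f))
}

# tibble constructor without quosure overhead, for hot paths
fast_tibble <- function(cols) {
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(length(cols[[1L]])))
}

new_eval_report <- function(task, mode, require_certainty, micro, per_class) {
  structure(list(task = task, mode = mode,
                 require_certainty = require_certainty,
                 micro = micro, per_class = per_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s (%s%s)>\n", x$task, x$mode,
              if (isTRUE(x$require_certainty)) ", +certainty" else ""))
  print(as.data.frame(x$micro), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.corpus_stats
#' @export
tidy.eval_report <- function(x, ...) {
  bind_rows(
    dplyr::mutate(x$micro, class = "<micro>", .before = 1L),
    x$per_class
  ) %>% mutate(task = x$task, mode = x$mode, .before = 1L)
}

#' @rdname tidy.corpus_stats
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::mutate(x$micro, task = x$task, mode = x$mode,
                require_certainty = x$require_certainty, .before = 1L)
}

# Coarsen a certainty value that may already be coarse.
coarse_certainty <- function(x, schema = default_schema()) {
  ifelse(x %in% schema$certainty_coarse & !(x %in% names(schema$certainty_map)),
         x, unname(schema$certainty_map[x]))
}

# Match relations of one document.  Entity arguments are first matched
# per mode; a predicted relation matches a gold relation when the types
# are equal, the arguments correspond (direction respected for
# directional types, order-free for symmetric ones), optionally the
# coarse certainty agrees, and optionally the trigger matches (envelope
# overlap per mode and same signaled type).  Greedy one-to-one.
match_relations <- function(gold_doc, pred_doc, mode,
                            require_certainty = FALSE,
                            require_trigger = FALSE,
                            schema = default_schema()) {
  g <- gold_doc$relations; p <- pred_doc$relations
  mm <- match_mentions(gold_doc$entities, pred_doc$entities, mode)
  # map pred entity id -> matched gold entity id
  id_map <- stats::setNames(gold_doc$entities$id[mm$tp$gold_ix],
                            pred_doc$entities$id[mm$tp$pred_ix])
  tmatch <- NULL
  if (require_trigger) {
    tmm <- match_mentions(gold_doc$triggers, pred_doc$triggers, mode)
    tmatch <- stats::setNames(gold_doc$triggers$id[tmm$tp$gold_ix],
                              pred_doc$triggers$id[tmm$tp$pred_ix])
  }
  ng <- nrow(g); np <- nrow(p)
  used_g <- logical(ng)
  pred_status <- rep("fp", np)
  pred_gold_ix <- rep(NA_integer_, np)
  # plain vectors: this loop sits under the bootstrap
  g_type <- g$type; g_agent <- g$agent; g_th1 <- g$theme1; g_th2 <- g$theme2
  g_trig <- g$trigger
  g_cert <- if (require_certainty) coarse_certainty(g$certainty, schema)
  p_type <- p$type; p_trig <- p$trigger
  p_cert <- if (require_certainty) coarse_certainty(p$certainty, schema)
  margs <- function(ids) unname(id_map[ids])
  p_agent_m <- margs(p$agent); p_th1_m <- margs(p$theme1)
  p_th2_m <- margs(p$theme2)
  for (j in seq_len(np)) {
    sig <- relation_signature(p_type[j], schema)
    for (i in seq_len(ng)) {
      if (used_g[i]) next
      if (g_type[i] != p_type[j]) next
      ok <- if (sig == "directional") {
        !is.na(p_agent_m[j]) && !is.na(p_th1_m[j]) &&
          identical(p_agent_m[j], g_agent[i]) &&
          identical(p_th1_m[j], g_th1[i])
      } else {
        pt <- c(p_th1_m[j], p_th2_m[j])
        !anyNA(pt) && setequal(pt, c(g_th1[i], g_th2[i]))
      }
      if (!ok) next
      if (require_trigger) {
        both_absent <- is.na(g_trig[i]) && is.na(p_trig[j])
        trig_ok <- both_absent ||
          (!is.na(g_trig[i]) && !is.na(p_trig[j]) &&
             identical(unname(tmatch[p_trig[j]]), g_trig[i]))
        if (!trig_ok) next
      }
      if (require_certainty && !identical(g_cert[i], p_cert[j])) next
      used_g[i] <- TRUE
      pred_status[j] <- "tp"
      pred_gold_ix[j] <- i
      break
    }
  }
  list(tp = sum(pred_status == "tp"), fp = sum(pred_status == "fp"),
       fn = sum(!used_g), pred_status = pred_status,
       pred_gold_ix = pred_gold_ix, gold_matched = used_g)
}

#' Score a task over aligned gold and predicted documents
#'
#' Micro-averaged precision/recall/F1 pooled over documents, plus
#' per-class counts.  Tasks: `"ner"` and `"trigger"` (mention matching
#' per mode), `"relation"` (argument matching per mode, type equality,
#' direction for directional types; trigger matching is never required),
#' and `"end2end"` (relation matching that additionally requires the
#' coarse certainty to agree).
#'
#' @param gold_docs,pred_docs Lists of [standoff_document()]s with
#'   aligned `doc_id`s.
#' @param task One of `"ner"`, `"trigger"`, `"relation"`, `"end2end"`.
#' @param mode `"strict"` or `"relaxed"`.
#' @param require_certainty Override the certainty requirement
#'   (defaults to `TRUE` for task `"end2end"`).
#' @param schema An [default_schema()] object.
#' @param detail Compute the per-class table (`TRUE` by default; the
#'   bootstrap disables it for speed).
#' @return An `eval_report`.
#' @export
score_task <- function(gold_docs, pred_docs,
                       task = c("ner", "trigger", "relation", "end2end"),
                       mode = c("strict", "relaxed"),
                       require_certainty = NULL,
                       schema = default_schema(), detail = TRUE) {
  task <- match.arg(task); mode <- match.arg(mode)
  if (is.null(require_certainty)) require_certainty <- task == "end2end"
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gid, pid) || length(gid) != length(pid)) {
    stop("gold and predicted document ids are not aligned", call. = FALSE)
  }
  pred_docs <- pred_docs[match(gid, pid)]
  tp <- fp <- fn <- 0L
  cls <- list()
  add_class <- function(class, dtp, dfp, dfn) {
    if (!detail) return(invisible())
    cls[[length(cls) + 1L]] <<- tibble(class = class, tp = dtp, fp = dfp, fn = dfn)
  }
  for (k in seq_along(gold_docs)) {
    gd <- gold_docs[[k]]; pd <- pred_docs[[k]]
    if (task %in% c("ner", "trigger")) {
      slot <- if (task == "ner") "entities" else "triggers"
      m <- match_mentions(gd[[slot]], pd[[slot]], mode)
      tp <- tp + nrow(m$tp); fp <- fp + length(m$fp); fn <- fn + length(m$fn)
      if (nrow(m$tp)) for (ty in unique(gd[[slot]]$type[m$tp$gold_ix]))
        add_class(ty, sum(gd[[slot]]$type[m$tp$gold_ix] == ty), 0L, 0L)
      if (length(m$fp)) for (ty in unique(pd[[slot]]$type[m$fp]))
        add_class(ty, 0L, sum(pd[[slot]]$type[m$fp] == ty), 0L)
      if (length(m$fn)) for (ty in unique(gd[[slot]]$type[m$fn]))
        add_class(ty, 0L, 0L, sum(gd[[slot]]$type[m$fn] == ty))
    } else {
      m <- match_relations(gd, pd, mode, require_certainty = require_certainty,
                           schema = schema)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      if (nrow(pd$relations)) {
        for (ty in unique(pd$relations$type)) {
          sel <- pd$relations$type == ty
          add_class(ty, sum(m$pred_status[sel] == "tp"),
                    sum(m$pred_status[sel] == "fp"), 0L)
        }
      }
      if (nrow(gd$relations)) {
        for (ty in unique(gd$relations$type[!m$gold_matched]))
          add_class(ty, 0L, 0L, sum(gd$relations$type[!m$gold_matched] == ty))
      }
    }
  }
  per_class <- if (length(cls)) {
    dplyr::bind_rows(cls) %>%
      group_by(.data$class) %>%
      summarise(dplyr::across(c("tp", "fp", "fn"), sum), .groups = "drop") %>%
      dplyr::rowwise() %>%
      dplyr::mutate(prf(.data$tp, .data$fp, .data$fn)[, c("precision", "recall", "f1")]) %>%
      ungroup()
  } else {
    tibble(class = character(), tp = integer(), fp = integer(), fn = integer(),
           precision = numeric(), recall = numeric(), f1 = numeric())
  }
  new_eval_report(task, mode, require_certainty, prf(tp, fp, fn), per_class)
}

#' Score factuality detection
#'
#' Default mode (`denominator = "all_gold"`): precision is computed over
#' correctly extracted relations (certainty among matched relations),
#' while the recall denominator is all gold relations, so missed
#' relations depress recall — the asymmetry seen when factuality is
#' near-perfect on found relations but many relations are missed.  The
#' alternate mode (`denominator = "matched"`) restricts both precision
#' and recall to matched relations.
#'
#' @param gold_docs,pred_docs Aligned document lists.
#' @param mode Matching mode for the underlying relation matching.
#' @param denominator `"all_gold"` (default) or `"matched"`.
#' @param schema An [default_schema()] object.
#' @return An `eval_report` with task `"factuality"`; the denominator
#'   mode is recorded in the `mode` field as `"<mode>/<denominator>"`.
#' @export
score_factuality <- function(gold_docs, pred_docs,
                             mode = c("strict", "relaxed"),
                             denominator = c("all_gold", "matched"),
                             schema = default_schema()) {
  mode <- match.arg(mode); denominator <- match.arg(denominator)
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gid, pid)) stop("unaligned document ids", call. = FALSE)
  pred_docs <- pred_docs[match(gid, pid)]
  n_matched <- 0L; n_correct <- 0L; n_gold <- 0L
  for (k in seq_along(gold_docs)) {
    gd <- gold_docs[[k]]; pd <- pred_docs[[k]]
    n_gold <- n_gold + nrow(gd$relations)
    m <- match_relations(gd, pd, mode, require_certainty = FALSE,
                         schema = schema)
    matched <- which(m$pred_status == "tp")
    n_matched <- n_matched + length(matched)
    for (j in matched) {
      gi <- m$pred_gold_ix[j]
      if (identical(coarse_certainty(gd$relations$certainty[gi], schema),
                    coarse_certainty(pd$relations$certainty[j], schema))) {
        n_correct <- n_correct + 1L
      }
    }
  }
  p <- if (n_matched > 0) n_correct / n_matched else 0
  r_den <- if (denominator == "all_gold") n_gold else n_matched
  r <- if (r_den > 0) n_correct / r_den else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  micro <- tibble(tp = n_correct, fp = n_matched - n_correct,
                  fn = r_den - n_correct, precision = p, recall = r, f1 = f)
  new_eval_report("factuality", paste(mode, denominator, sep = "/"),
                  FALSE, micro,
                  tibble(class = character(), tp = integer(), fp = integer(),
                         fn = integer(), precision = numeric(),
                         recall = numeric(), f1 = numeric()))
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples documents with replacement `B` times and recomputes the
#' pooled micro statistic on each replicate; deterministic under a fixed
#' seed.
#'
#' @param gold_docs,pred_docs Aligned document lists.
#' @param task,mode,require_certainty Passed to [score_task()].
#' @param statistic `"f1"`, `"precision"` or `"recall"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @param schema An [default_schema()] object.
#' @return A one-row tibble: `statistic`, `estimate`, `lower`, `upper`,
#'   `level`, `B`, `seed`.
#' @export
bootstrap_ci <- function(gold_docs, pred_docs, task = "ner", mode = "strict",
                         require_certainty = NULL, statistic = "f1",
                         B = 1000L, seed = 1L, level = 0.95,
                         schema = default_schema()) {
  est <- score_task(gold_docs, pred_docs, task, mode,
                    require_certainty, schema)$micro[[statistic]]
  n <- length(gold_docs)
  if (n < 2L) {
    warning("bootstrap over a single document: degenerate interval",
            call. = FALSE)
    return(tibble(statistic = statistic, estimate = est, lower = est,
                  upper = est, level = level, B = B, seed = seed))
  }
  pid <- vapply(pred_docs, `[[`, "", "doc_id")
  gid <- vapply(gold_docs, `[[`, "", "doc_id")
  pred_docs <- pred_docs[match(gid, pid)]
  old <- .Random.seed_get()
  set.seed(seed)
  stats_b <- vapply(seq_len(B), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    score_task(rename_docs(gold_docs[ix]), rename_docs(pred_docs[ix]),
               task, mode, require_certainty, schema)$micro[[statistic]]
  }, numeric(1L))
  .Random.seed_set(old)
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(statistic = statistic, estimate = est, lower = q[1L], upper = q[2L],
         level = level, B = B, seed = seed)
}

# Bootstrap replicates repeat documents; give replicates unique ids so
# alignment checks pass while keeping gold/pred paired by position.
rename_docs <- function(docs) {
  lapply(seq_along(docs), function(i) {
    d <- docs[[i]]; d$doc_id <- paste0(d$doc_id, "#", i); d
  })
}

#' Inter-annotator agreement between two annotation sets
#'
#' F1 of one annotator's annotations scored against the other's.  Exact
#' agreement uses strict boundary matching, partial agreement requires
#' the type to match while allowing overlapping spans.  Relation
#' agreement requires argument matching (per mode) and, when
#' `require_trigger` applies, a matching trigger (overlap per mode, same
#' signaled type).
#'
#' @param docs_a,docs_b Lists of [standoff_document()]s over the same
#'   documents, one per annotator.
#' @param schema An [default_schema()] object.
#' @return An `iaa_report`: tibble with one row per (task, mode,
#'   trigger-requirement) combination.
#' @export
compute_iaa <- function(docs_a, docs_b, schema = default_schema()) {
  ida <- vapply(docs_a, `[[`, "", "doc_id")
  idb <- vapply(docs_b, `[[`, "", "doc_id")
  if (!setequal(ida, idb)) stop("annotators cover different documents",
                                call. = FALSE)
  docs_b <- docs_b[match(ida, idb)]
  rows <- list()
  for (mode in c("strict", "relaxed")) {
    lab <- if (mode == "strict") "exact" else "partial"
    ent <- score_task(docs_b, docs_a, "ner", mode, schema = schema)
    rows[[length(rows) + 1L]] <- tibble(task = "entity", agreement = lab,
                                        require_trigger = FALSE,
                                        f1 = ent$micro$f1)
    for (rt in c(TRUE, FALSE)) {
      tp <- fp <- fn <- 0L
      for (k in seq_along(docs_a)) {
        m <- match_relations(docs_b[[k]], docs_a[[k]], mode,
                             require_trigger = rt, schema = schema)
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      }
      rows[[length(rows) + 1L]] <- tibble(task = "relation", agreement = lab,
                                          require_trigger = rt,
                                          f1 = prf(tp, fp, fn)$f1)
    }
  }
  structure(dplyr::bind_rows(rows), class = c("iaa_report", "tbl_df", "tbl",
                                              "data.frame"))
}
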