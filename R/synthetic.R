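# Deterministic generator of schema-conformant synthetic corpora with an
# exact ground-truth ledger.  Documents instantiate templates such as
# "[Nutrient] [cue] [trigger] [Microorganism] in [Population]." so that
# every relation's trigger cue appears in-sentence and certainty is
# realized by deterministic cue words.

# Type-revealing surface vocabularies: every surface word belongs to
# exactly one entity type, so span labels are recoverable from the text.
.entity_vocab_revealing <- list(
  Food = c("oatmeal", "yogurt", "walnuts", "lentils", "kefir", "barley"),
  Nutrient = c("inulin", "pectin", "polydextrose", "arabinoxylan", "fructan",
               "galactooligosaccharide"),
  DietPattern = c("Mediterranean diet", "ketogenic diet", "vegetarian diet",
                  "low-FODMAP diet"),
  Microorganism = c("Bifidobacterium", "Lactobacillus", "Akkermansia",
                    "Roseburia", "Faecalibacterium", "Prevotella"),
  DiversityMetric = c("Shannon diversity", "Chao1 richness", "evenness"),
  Metabolite = c("butyrate", "propionate", "acetate", "urolithin", "indole"),
  Physiology = c("satiety", "motility", "adiposity", "inflammation"),
  Disease = c("obesity", "diabetes", "colitis", "atherosclerosis"),
  Measurement = c("cholesterol", "triglycerides", "glycemia", "calprotectin",
                  "zonulin"),
  Enzyme = c("amylase", "lipase", "xylanase", "protease"),
  Gene = c("FUT2", "APOE", "TLR4", "NOD2"),
  Chemical = c("polyphenol", "flavonoid", "anthocyanin", "catechin"),
  Methodology = c("metagenomics", "qPCR", "ELISA", "spectrometry"),
  Population = c("adults", "infants", "athletes", "volunteers", "patients"),
  Biospecimen = c("feces", "plasma", "serum", "saliva")
)

# Trigger cue lexicon: each of the 13 relation types maps to cue words
# that appear in-sentence and justify the relation.
.trigger_vocab_revealing <- list(
  affects = c("modulated", "influenced"),
  improves = c("ameliorated", "improved"),
  worsens = c("exacerbated", "aggravated"),
  associated_with = c("correlated", "co-occurred"),
  pos_associated_with = c("paralleled", "tracked"),
  neg_associated_with = c("anticorrelated", "opposed"),
  interacts_with = c("interacted", "synergized"),
  increases = c("increased", "elevated"),
  decreases = c("decreased", "reduced"),
  causes = c("caused", "induced"),
  prevents = c("prevented", "averted"),
  predisposes = c("predisposed"),
  has_component = c("contained", "comprised")
)

# Certainty cue words inserted before the trigger; the fine level is
# deterministically recoverable from the cue.
.certainty_cues <- c(
  Factual = "", Probable = "likely", Possible = "possibly",
  Doubtful = "questionably", Negated = "never", Unknown = "reportedly"
)

# Shared ambiguous surfaces used in "ambiguous" vocabulary mode.
.ambiguous_pool <- c("profile", "signature", "fraction", "cluster")

#' Synthetic corpus generator configuration
#'
#' Defaults encode the statistical structure the pipeline assumes: ~5%
#' nested mentions (maximum depth 2), ~2% discontinuous mentions, ~11%
#' cross-sentence relations, and a certainty distribution dominated by
#' Factual with Unknown carrying most of the uncertain mass (74% of it).
#'
#' @param n_docs Number of title/abstract documents.
#' @param n_results_docs Number of results-section documents.
#' @param sentences_per_doc Sentences per document.
#' @param rate_nesting Target fraction of entity mentions that are nested.
#' @param rate_discontinuous Target fraction of discontinuous mentions.
#' @param rate_cross_sentence Target fraction of cross-sentence relations.
#' @param certainty_probs Named probability vector over the six fine
#'   certainty levels.
#' @param relation_probs Named probability vector over the 13 relation
#'   types (defaults echo a corpus where increases, affects and decreases
#'   dominate).
#' @param vocab_mode `"type_revealing"` (every surface word belongs to one
#'   type) or `"ambiguous"` (some surfaces shared across types).
#' @param seed Generator seed; the same seed yields a byte-identical
#'   corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_docs = 250L, n_results_docs = 0L,
                             sentences_per_doc = 3L,
                             rate_nesting = 0.05,
                             rate_discontinuous = 0.02,
                             rate_cross_sentence = 0.11,
                             certainty_probs = NULL,
                             relation_probs = NULL,
                             vocab_mode = c("type_revealing", "ambiguous"),
                             seed = 1L) {
  vocab_mode <- match.arg(vocab_mode)
  if (is.null(certainty_probs)) {
    # 30% uncertain mass split 74/19/6/1 across Unknown/Possible/
    # Probable/Doubtful
    certainty_probs <- c(Factual = 0.62, Negated = 0.08,
                         Unknown = 0.30 * 0.74, Possible = 0.30 * 0.19,
                         Probable = 0.30 * 0.06, Doubtful = 0.30 * 0.01)
  }
  if (is.null(relation_probs)) {
    relation_probs <- c(
      increases = 0.27, affects = 0.22, decreases = 0.18,
      pos_associated_with = 0.08, neg_associated_with = 0.06,
      improves = 0.05, associated_with = 0.05, has_component = 0.04,
      interacts_with = 0.015, causes = 0.01, prevents = 0.01,
      predisposes = 0.01, worsens = 0.005
    )
  }
  rates <- c(rate_nesting, rate_discontinuous, rate_cross_sentence)
  stopifnot(all(rates >= 0), all(rates <= 1),
            abs(sum(certainty_probs) - 1) < 1e-8,
            abs(sum(relation_probs) - 1) < 1e-8)
  structure(list(
    n_docs = as.integer(n_docs), n_results_docs = as.integer(n_results_docs),
    sentences_per_doc = as.integer(sentences_per_doc),
    rate_nesting = rate_nesting, rate_discontinuous = rate_discontinuous,
    rate_cross_sentence = rate_cross_sentence,
    certainty_probs = certainty_probs, relation_probs = relation_probs,
    vocab_mode = vocab_mode, seed = as.integer(seed)
  ), class = "generator_config")
}

# ---- sentence assembly ------------------------------------------------------

# Mutable sentence buffer: appends word tokens separated by single
# spaces and records character offsets (relative to the sentence).
new_sentence_buffer <- function() {
  env <- new.env(parent = emptyenv())
  env$txt <- ""
  env$add_tok <- function(s) {
    if (nzchar(env$txt)) env$txt <- paste0(env$txt, " ")
    st <- nchar(env$txt)
    env$txt <- paste0(env$txt, s)
    c(st, nchar(env$txt))
  }
  env$add_phrase <- function(s) { # multiword surface, one fragment
    words <- strsplit(s, " ", fixed = TRUE)[[1L]]
    sp <- vapply(words, env$add_tok, integer(2L))
    c(sp[1L, 1L], sp[2L, ncol(sp)])
  }
  env
}

pick <- function(x, n = 1L) x[sample.int(length(x), n)]

sample_surface <- function(vocab, type, mode) {
  if (mode == "ambiguous" && stats::runif(1) < 0.3) {
    return(pick(.ambiguous_pool))
  }
  pick(vocab[[type]])
}

.agent_types <- c("Food", "Nutrient", "DietPattern", "Chemical")
.theme_types <- c("Microorganism", "Metabolite", "Measurement", "Physiology",
                  "Disease", "DiversityMetric", "Enzyme", "Gene", "Methodology")

# ---- corpus generation ------------------------------------------------------

#' Generate a synthetic standoff corpus with an exact ground-truth ledger
#'
#' Every sentence instantiates a relation template; the relation's
#' trigger cue appears in-sentence and certainty is realized by a
#' deterministic cue word (e.g., "never" before the trigger for Negated,
#' "possibly" for Possible).  Nested mentions (depth 2), discontinuous
#' mentions and cross-sentence relations are injected at the configured
#' rates.  The ledger records the exact realized counts and the sentence
#' boundaries of every document.
#'
#' @param config A [generator_config()].
#' @param dir Optional directory: when given, standoff files
#'   (`.txt`/`.ann`), `manifest.json` and `ledger.json` are written there.
#' @return A list with elements `corpus` (list of
#'   [standoff_document()]s), `manifest` (tibble) and `ledger` (list of
#'   exact counts; class `generator_ledger`).
#' @export
generate_corpus <- function(config = generator_config(), dir = NULL) {
  vocab <- .entity_vocab_revealing
  if (any(lengths(vocab) == 0L)) stop("empty vocabulary", call. = FALSE)
  trig_vocab <- .trigger_vocab_revealing
  schema <- default_schema()

  old <- .Random.seed_get()
  set.seed(config$seed)
  on.exit(.Random.seed_set(old), add = TRUE)

  # derived per-slot probabilities hitting the configured global rates
  # (3 base mentions per sentence; nesting adds one; symmetric sentences
  # carry no nesting slot)
  p_sym <- sum(config$relation_probs[schema$symmetric_types])
  p_dir <- 1 - p_sym
  q_nest <- min(1, 3 * config$rate_nesting /
                  (p_dir * (1 - config$rate_nesting)))
  p_disc <- min(1, config$rate_discontinuous * (3 + p_dir * q_nest))
  S <- config$sentences_per_doc
  p_cross <- if (S > 1L && config$rate_cross_sentence > 0) {
    min(1, config$rate_cross_sentence * S /
          ((1 - config$rate_cross_sentence) * (S - 1L)))
  } else 0

  n_nested <- 0L; n_disc <- 0L; n_cross <- 0L
  boundaries <- list()

  make_doc <- function(doc_id, section) {
    ents <- list(); trgs <- list(); rels <- list()
    sent_texts <- character(S)
    sent_anchor <- vector("list", S) # per-sentence entity row indices
    offset <- 0L
    add_ent <- function(type, frags, sentence) {
      ents[[length(ents) + 1L]] <<- list(type = type, frags = frags,
                                         sentence = sentence)
      length(ents)
    }
    for (si in seq_len(S)) {
      buf <- new_sentence_buffer()
      rel_type <- sample(names(config$relation_probs), 1L,
                         prob = config$relation_probs)
      sym <- rel_type %in% schema$symmetric_types
      certainty <- sample(names(config$certainty_probs), 1L,
                          prob = config$certainty_probs)
      cue <- .certainty_cues[[certainty]]
      local_ents <- integer()

      emit_mention <- function(type, disc_ok = FALSE, nest_ok = FALSE) {
        if (nest_ok && stats::runif(1) < q_nest) {
          f1 <- buf$add_tok("fortified")
          inner_type <- "Nutrient"
          inner_sp <- buf$add_phrase(sample_surface(vocab, inner_type,
                                                    config$vocab_mode))
          f3 <- buf$add_tok("blend")
          inner <- add_ent(inner_type, span_location(inner_sp[1L], inner_sp[2L]), si)
          outer <- add_ent("Food", span_location(f1[1L], f3[2L]), si)
          n_nested <<- n_nested + 1L
          return(outer)
        }
        if (disc_ok && stats::runif(1) < p_disc) {
          wA <- buf$add_tok("fecal")
          buf$add_tok("overall")
          wB <- buf$add_phrase(sample_surface(vocab, type, config$vocab_mode))
          n_disc <<- n_disc + 1L
          return(add_ent(type, span_location(c(wA[1L], wB[1L]),
                                             c(wA[2L], wB[2L])), si))
        }
        sp <- buf$add_phrase(sample_surface(vocab, type, config$vocab_mode))
        add_ent(type, span_location(sp[1L], sp[2L]), si)
      }

      if (!sym) {
        a_type <- if (rel_type == "has_component") "Food" else pick(.agent_types)
        t_type <- if (rel_type == "has_component") "Nutrient" else pick(.theme_types)
        agent <- emit_mention(a_type, nest_ok = TRUE)
        if (nzchar(cue)) buf$add_tok(cue)
        tr_sp <- buf$add_tok(pick(trig_vocab[[rel_type]]))
        theme <- emit_mention(t_type, disc_ok = TRUE)
        buf$add_tok("in")
        popn <- emit_mention("Population")
        local_ents <- c(agent, theme, popn)
        trgs[[length(trgs) + 1L]] <- list(type = rel_type,
                                          frags = span_location(tr_sp[1L], tr_sp[2L]),
                                          sentence = si)
        rels[[length(rels) + 1L]] <- list(
          type = rel_type, agent = agent, theme1 = theme, theme2 = NA_integer_,
          trigger = length(trgs), certainty = certainty, cross = FALSE)
      } else {
        e1 <- emit_mention(pick(.theme_types), disc_ok = TRUE)
        if (nzchar(cue)) buf$add_tok(cue)
        tr_sp <- buf$add_tok(pick(trig_vocab[[rel_type]]))
        buf$add_tok("with")
        e2 <- emit_mention(pick(.theme_types))
        buf$add_tok("in")
        bio <- emit_mention("Biospecimen")
        buf$add_tok("samples")
        local_ents <- c(e1, e2, bio)
        trgs[[length(trgs) + 1L]] <- list(type = rel_type,
                                          frags = span_location(tr_sp[1L], tr_sp[2L]),
                                          sentence = si)
        rels[[length(rels) + 1L]] <- list(
          type = rel_type, agent = NA_integer_, theme1 = e1, theme2 = e2,
          trigger = length(trgs), certainty = certainty, cross = FALSE)
      }
      buf$txt <- paste0(buf$txt, ".")
      sent_texts[si] <- buf$txt
      sent_anchor[[si]] <- local_ents
      # shift this sentence's fresh annotations by the document offset
      shift <- offset
      for (k in seq_along(ents)) {
        if (ents[[k]]$sentence == si && is.null(ents[[k]]$shifted)) {
          ents[[k]]$frags <- ents[[k]]$frags + shift
          ents[[k]]$shifted <- TRUE
        }
      }
      for (k in seq_along(trgs)) {
        if (trgs[[k]]$sentence == si && is.null(trgs[[k]]$shifted)) {
          trgs[[k]]$frags <- trgs[[k]]$frags + shift
          trgs[[k]]$shifted <- TRUE
        }
      }
      offset <- offset + nchar(buf$txt) + 1L # joining space
    }
    # cross-sentence relations between adjacent sentences
    for (si in seq_len(S - 1L)) {
      if (stats::runif(1) < p_cross) {
        a <- sent_anchor[[si]][2L]     # theme-side mention of sentence si
        b <- sent_anchor[[si + 1L]][1L] # agent-side mention of sentence si+1
        rels[[length(rels) + 1L]] <- list(
          type = "associated_with", agent = NA_integer_, theme1 = a,
          theme2 = b, trigger = NA_integer_, certainty = "Unknown",
          cross = TRUE)
        n_cross <<- n_cross + 1L
      }
    }
    text <- paste(sent_texts, collapse = " ")
    # boundary after sentence k sits right after its final terminator;
    # the joining space belongs to the next sentence's range
    b <- cumsum(nchar(sent_texts)) + (seq_len(S) - 1L)
    bounds <- tibble(start = c(0L, b[-S]), end = b)
    boundaries[[doc_id]] <<- bounds

    ent_tb <- dplyr::bind_rows(lapply(seq_along(ents), function(k) {
      e <- ents[[k]]
      tibble(id = paste0("T", k), type = e$type, fragments = list(e$frags),
             surface = slice_surface(text, e$frags))
    }))
    trg_tb <- dplyr::bind_rows(lapply(seq_along(trgs), function(k) {
      t <- trgs[[k]]
      tibble(id = paste0("T", length(ents) + k), type = t$type,
             fragments = list(t$frags), surface = slice_surface(text, t$frags))
    }))
    if (is.null(ent_tb)) ent_tb <- empty_mentions()
    if (is.null(trg_tb)) trg_tb <- empty_mentions()
    rel_tb <- dplyr::bind_rows(lapply(seq_along(rels), function(k) {
      r <- rels[[k]]
      tibble(
        id = paste0(if (is.na(r$trigger)) "R" else "E", k),
        type = r$type,
        agent = if (is.na(r$agent)) NA_character_ else paste0("T", r$agent),
        theme1 = if (is.na(r$theme1)) NA_character_ else paste0("T", r$theme1),
        theme2 = if (is.na(r$theme2)) NA_character_ else paste0("T", r$theme2),
        trigger = if (is.na(r$trigger)) NA_character_ else
          paste0("T", length(ents) + r$trigger),
        certainty = r$certainty, sentence_bound = !r$cross
      )
    }))
    if (is.null(rel_tb)) rel_tb <- empty_relations()
    standoff_document(doc_id, text, section, entities = ent_tb,
                      triggers = trg_tb, relations = rel_tb,
                      sentences = bounds)
  }

  ids_ta <- sprintf("d%04d", seq_len(config$n_docs))
  ids_res <- if (config$n_results_docs > 0L)
    sprintf("r%04d", seq_len(config$n_results_docs)) else character()
  corpus <- c(lapply(ids_ta, make_doc, section = "title_abstract"),
              lapply(ids_res, make_doc, section = "results"))
  names(corpus) <- c(ids_ta, ids_res)

  ents_all <- entity_table(corpus)
  trgs_all <- trigger_table(corpus)
  rels_all <- relation_table(corpus)
  ledger <- structure(list(
    n_docs = length(corpus),
    n_docs_by_section = table(vapply(corpus, `[[`, "", "section")),
    n_sentences = length(corpus) * S,
    n_entities = nrow(ents_all),
    n_triggers = nrow(trgs_all),
    n_relations = nrow(rels_all),
    entity_type_counts = table(factor(ents_all$type, levels = schema$entity_types)),
    trigger_type_counts = table(factor(trgs_all$type, levels = schema$relation_types)),
    relation_type_counts = table(factor(rels_all$type, levels = schema$relation_types)),
    certainty_counts = table(factor(rels_all$certainty, levels = schema$certainty_fine)),
    n_nested = n_nested, n_discontinuous = n_disc, n_cross_sentence = n_cross,
    sentence_boundaries = boundaries,
    config = config
  ), class = "generator_ledger")

  manifest <- tibble(
    doc_id = names(corpus),
    section = vapply(corpus, `[[`, "", "section"),
    split = NA_character_
  )
  if (!is.null(dir)) {
    write_corpus(corpus, dir, manifest)
    jsonlite::write_json(
      list(n_docs = ledger$n_docs, n_entities = ledger$n_entities,
           n_triggers = ledger$n_triggers, n_relations = ledger$n_relations,
           n_nested = ledger$n_nested,
           n_discontinuous = ledger$n_discontinuous,
           n_cross_sentence = ledger$n_cross_sentence,
           entity_type_counts = as.list(ledger$entity_type_counts),
           relation_type_counts = as.list(ledger$relation_type_counts),
           certainty_counts = as.list(ledger$certainty_counts)),
      file.path(dir, "ledger.json"), auto_unbox = TRUE)
  }
  list(corpus = corpus, manifest = manifest, ledger = ledger)
}

#' @export
print.generator_ledger <- function(x, ...) {
  cat(sprintf("<generator_ledger: %d docs, %d entities (%d nested, %d discont.), %d triggers, %d relations (%d cross-sentence)>\n",
              x$n_docs, x$n_entities, x$n_nested, x$n_discontinuous,
              x$n_triggers, x$n_relations, x$n_cross_sentence))
  invisible(x)
}

#' Split a corpus manifest into train/dev/test
#'
#' Document-level split, deterministic under the seed.  When
#' `results_train_only = TRUE` (the default), results-section documents
#' are assigned to the training split regardless of the draw, mirroring
#' the practice of using results-section annotations for training only;
#' the title/abstract fractions are applied to the remaining documents.
#'
#' @param manifest Tibble with `doc_id` and `section`.
#' @param fractions Length-3 numeric (train, dev, test) summing to 1.
#' @param seed Split seed.
#' @param results_train_only Restrict results documents to train.
#' @return The manifest with its `split` column filled in.
#' @export
make_split <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       results_train_only = TRUE) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  old <- .Random.seed_get()
  set.seed(seed)
  on.exit(.Random.seed_set(old), add = TRUE)
  manifest$split <- NA_character_
  pool <- if (results_train_only) which(manifest$section != "results") else
    seq_len(nrow(manifest))
  manifest$split[setdiff(seq_len(nrow(manifest)), pool)] <- "train"
  n <- length(pool)
  n_train <- round(fractions[1L] * n)
  n_dev <- round(fractions[2L] * n)
  n_test <- n - n_train - n_dev
  if (n_test < 0L) { n_dev <- n_dev + n_test; n_test <- 0L }
  lab <- c(rep("train", n_train), rep("dev", n_dev), rep("test", n_test))
  manifest$split[pool[sample.int(n)]] <- lab
  manifest
}
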