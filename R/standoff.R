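#' @importFrom dplyr %>% mutate filter select arrange bind_rows left_join group_by summarise ungroup n
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# ---- span locations ---------------------------------------------------------

# A span location is an integer matrix with columns start, end; 0-based
# half-open character offsets, one row per fragment.  More than one row
# marks a discontinuous mention.
span_location <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  if (nrow(m) < 1L) stop("a span needs at least one fragment", call. = FALSE)
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (any(m[, 1L] >= m[, 2L])) {
    stop("each fragment must have start < end", call. = FALSE)
  }
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop("span fragments must not overlap", call. = FALSE)
  }
  m
}

format_fragments <- function(frags) {
  paste(paste(frags[, 1L], frags[, 2L]), collapse = ";")
}

parse_fragments <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  nums <- lapply(parts, function(p) as.integer(strsplit(trimws(p), "[ \t]+")[[1L]]))
  if (any(vapply(nums, length, 1L) != 2L)) {
    stop("malformed span offsets: ", s, call. = FALSE)
  }
  m <- do.call(rbind, nums)
  span_location(m[, 1L], m[, 2L])
}

# Text slice covered by a span; brat joins discontinuous fragments with a
# single space.
slice_surface <- function(text, frags) {
  paste(substring(text, frags[, 1L] + 1L, frags[, 2L]), collapse = " ")
}

span_envelope <- function(frags) c(min(frags[, 1L]), max(frags[, 2L]))

# ---- document container -----------------------------------------------------

empty_mentions <- function() {
  tibble(id = character(), type = character(),
         fragments = list(), surface = character())
}

empty_relations <- function() {
  tibble(id = character(), type = character(), agent = character(),
         theme1 = character(), theme2 = character(), trigger = character(),
         certainty = character(), sentence_bound = logical())
}

#' Construct a sectioned standoff document
#'
#' A `standoff_document` holds the text of one publication section together
#' with its annotations: entity mentions, relation triggers, and typed
#' relations with optional trigger anchors and certainty levels.  Mentions
#' may be nested or discontinuous; offsets are 0-based half-open character
#' offsets into `text`.
#'
#' @param doc_id Document identifier.
#' @param text Section text.
#' @param section `"title_abstract"` or `"results"`.
#' @param entities,triggers Tibbles with columns `id`, `type`, `fragments`
#'   (list of two-column start/end matrices) and `surface`.
#' @param relations Tibble with columns `id`, `type`, `agent`, `theme1`,
#'   `theme2`, `trigger`, `certainty`, `sentence_bound`.
#' @param sentences Optional tibble of sentence boundaries (`start`, `end`).
#' @return A `standoff_document` object.
#' @export
standoff_document <- function(doc_id, text, section = "title_abstract",
                              entities = empty_mentions(),
                              triggers = empty_mentions(),
                              relations = empty_relations(),
                              sentences = NULL) {
  stopifnot(section %in% c("title_abstract", "results"))
  structure(
    list(doc_id = doc_id, section = section, text = text,
         sentences = sentences, entities = as_tibble(entities),
         triggers = as_tibble(triggers), relations = as_tibble(relations)),
    class = "standoff_document"
  )
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document %s [%s], %d chars>\n",
              x$doc_id, x$section, nchar(x$text)))
  cat(sprintf("  entities: %d  triggers: %d  relations: %d  sentences: %s\n",
              nrow(x$entities), nrow(x$triggers), nrow(x$relations),
              if (is.null(x$sentences)) "unsegmented" else nrow(x$sentences)))
  invisible(x)
}

# ---- parsing ----------------------------------------------------------------

#' Parse a brat standoff annotation file against its text
#'
#' Reads text-bound (`T`), event (`E`), relation (`R`) and attribute (`A`)
#' lines.  Text-bound annotations whose label is an entity type become
#' entity mentions; those whose label is a relation type become triggers.
#' Both relation dialects are accepted: event-style lines anchored on a
#' trigger (`TYPE:Tk Agent:Ti Theme:Tj`) and plain relation lines with an
#' optional `Trigger:` argument.  Certainty is carried by attribute lines
#' attached to the relation id.
#'
#' @param txt_content The document text (single string).
#' @param ann_content The standoff annotation content (single string, may be
#'   empty).
#' @param schema An [default_schema()] object.
#' @param doc_id,section Document metadata.
#' @return A [standoff_document()].
#' @export
parse_standoff <- function(txt_content, ann_content,
                           schema = default_schema(),
                           doc_id = "doc", section = "title_abstract") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  n_text <- nchar(txt_content)

  ents <- list(); trgs <- list(); rels <- list(); attrs <- list()

  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- fields[[1L]]
    tag <- substr(id, 1L, 1L)
    if (tag == "T") {
      if (length(fields) < 2L) stop("malformed text-bound line: ", ln, call. = FALSE)
      head_parts <- regmatches(fields[[2L]],
                               regexpr("^\\S+", fields[[2L]]))
      type <- head_parts
      off <- sub("^\\S+\\s+", "", fields[[2L]])
      frags <- parse_fragments(off)
      if (max(frags[, 2L]) > n_text) {
        stop("offset out of range in line: ", ln, call. = FALSE)
      }
      surface <- slice_surface(txt_content, frags)
      given <- if (length(fields) >= 3L) fields[[3L]] else ""
      if (nzchar(given) && given != surface) {
        stop("surface/text mismatch in line: ", ln,
             " (text slice is \"", surface, "\")", call. = FALSE)
      }
      if (type %in% schema$entity_types) {
        ents[[length(ents) + 1L]] <-
          tibble(id = id, type = type, fragments = list(frags), surface = surface)
      } else if (type %in% schema$relation_types) {
        trgs[[length(trgs) + 1L]] <-
          tibble(id = id, type = type, fragments = list(frags), surface = surface)
      } else {
        stop("unknown annotation type \"", type, "\" in line: ", ln, call. = FALSE)
      }
    } else if (tag %in% c("E", "R")) {
      args <- strsplit(trimws(fields[[2L]]), "\\s+")[[1L]]
      kv <- strsplit(args, ":", fixed = TRUE)
      keys <- vapply(kv, `[[`, "", 1L)
      vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else NA_character_, "")
      # event dialect: first token is TYPE:Ttrigger
      event_style <- !is.na(vals[[1L]]) && grepl("^T", vals[[1L]]) &&
        keys[[1L]] %in% schema$relation_types
      if (event_style) {
        type <- keys[[1L]]; trig <- vals[[1L]]
        keys <- keys[-1L]; vals <- vals[-1L]
      } else {
        type <- keys[[1L]]; trig <- NA_character_
        keys <- keys[-1L]; vals <- vals[-1L]
        if ("Trigger" %in% keys) {
          trig <- vals[keys == "Trigger"][[1L]]
          vals <- vals[keys != "Trigger"]; keys <- keys[keys != "Trigger"]
        }
      }
      if (!type %in% schema$relation_types) {
        stop("unknown relation type \"", type, "\" in line: ", ln, call. = FALSE)
      }
      agent <- if ("Agent" %in% keys) vals[keys == "Agent"][[1L]] else NA_character_
      themes <- vals[grepl("^Theme", keys)]
      rels[[length(rels) + 1L]] <- tibble(
        id = id, type = type, agent = agent,
        theme1 = if (length(themes) >= 1L) themes[[1L]] else NA_character_,
        theme2 = if (length(themes) >= 2L) themes[[2L]] else NA_character_,
        trigger = trig, certainty = NA_character_, sentence_bound = NA
      )
    } else if (tag == "A") {
      args <- strsplit(trimws(fields[[2L]]), "\\s+")[[1L]]
      if (length(args) >= 3L && args[[1L]] %in% c("Factuality", "Certainty")) {
        attrs[[length(attrs) + 1L]] <- tibble(target = args[[2L]], value = args[[3L]])
      }
    } else {
      stop("unsupported standoff line: ", ln, call. = FALSE)
    }
  }

  entities <- if (length(ents)) bind_rows(ents) else empty_mentions()
  triggers <- if (length(trgs)) bind_rows(trgs) else empty_mentions()
  relations <- if (length(rels)) bind_rows(rels) else empty_relations()

  if (nrow(relations) > 0L) {
    relations$certainty <- "Unknown"
    if (length(attrs)) {
      at <- bind_rows(attrs)
      bad <- setdiff(unique(at$value), schema$certainty_fine)
      if (length(bad)) {
        stop("unknown certainty level(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      idx <- match(relations$id, at$target)
      relations$certainty[!is.na(idx)] <- at$value[idx[!is.na(idx)]]
    }
    known <- c(entities$id, triggers$id)
    refs <- c(relations$agent, relations$theme1, relations$theme2, relations$trigger)
    dangling <- setdiff(refs[!is.na(refs)], known)
    if (length(dangling)) {
      stop("relation argument(s) refer to unknown annotation(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }

  standoff_document(doc_id, txt_content, section,
                    entities = entities, triggers = triggers,
                    relations = relations)
}

# ---- writing ----------------------------------------------------------------

#' Serialize a document to brat standoff
#'
#' Inverse of [parse_standoff()]: emits text-bound lines for entities and
#' triggers, event-style lines for relations anchored on a trigger, plain
#' relation lines otherwise, and certainty attribute lines for relations
#' whose fine-grained certainty is not `Unknown`.
#'
#' @param doc A [standoff_document()].
#' @return A list with elements `txt` and `ann` (single strings).
#' @export
write_standoff <- function(doc) {
  known <- c(doc$entities$id, doc$triggers$id)
  if (nrow(doc$relations) > 0L) {
    refs <- c(doc$relations$agent, doc$relations$theme1,
              doc$relations$theme2, doc$relations$trigger)
    dangling <- setdiff(refs[!is.na(refs)], known)
    if (length(dangling)) {
      stop("cannot serialize: dangling reference(s) ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  t_line <- function(m) {
    sprintf("%s\t%s %s\t%s", m$id, m$type, format_fragments(m$fragments[[1L]]),
            m$surface)
  }
  lines <- character()
  for (i in seq_len(nrow(doc$entities))) lines <- c(lines, t_line(doc$entities[i, ]))
  for (i in seq_len(nrow(doc$triggers))) lines <- c(lines, t_line(doc$triggers[i, ]))
  attr_lines <- character(); a_ix <- 0L
  for (i in seq_len(nrow(doc$relations))) {
    r <- doc$relations[i, ]
    args <- character()
    if (!is.na(r$agent)) args <- c(args, paste0("Agent:", r$agent))
    if (!is.na(r$theme1)) args <- c(args, paste0("Theme:", r$theme1))
    if (!is.na(r$theme2)) args <- c(args, paste0("Theme2:", r$theme2))
    if (!is.na(r$trigger)) {
      lines <- c(lines, sprintf("%s\t%s:%s %s", r$id, r$type, r$trigger,
                                paste(args, collapse = " ")))
    } else {
      lines <- c(lines, sprintf("%s\t%s %s", r$id, r$type,
                                paste(args, collapse = " ")))
    }
    if (!is.na(r$certainty) && r$certainty != "Unknown") {
      a_ix <- a_ix + 1L
      attr_lines <- c(attr_lines,
                      sprintf("A%d\tFactuality %s %s", a_ix, r$id, r$certainty))
    }
  }
  list(txt = doc$text,
       ann = paste(c(lines, attr_lines), collapse = "\n"))
}

# ---- validation -------------------------------------------------------------

#' Validate a document against the annotation schema
#'
#' Checks type vocabularies, relation argument signatures (directional
#' types take exactly one Agent and one Theme; symmetric types take two
#' Themes and no Agent), certainty levels, offset ranges, surface/text
#' agreement, fragment well-formedness, reference integrity, and mention
#' nesting depth.  Violations are returned as data, not raised.
#'
#' @param doc A [standoff_document()].
#' @param schema An [default_schema()] object.
#' @param max_depth Nesting depth above which a warning-level violation is
#'   recorded (default 2).
#' @return A tibble with columns `rule`, `severity`, `id`, `message`;
#'   zero rows iff the document is valid.
#' @export
validate_document <- function(doc, schema = default_schema(), max_depth = 2L) {
  v <- list()
  add <- function(rule, severity, id, message) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, severity = severity,
                                   id = id, message = message)
  }
  n_text <- nchar(doc$text)
  check_mentions <- function(tb, vocab, what) {
    for (i in seq_len(nrow(tb))) {
      m <- tb[i, ]
      if (!m$type %in% vocab) {
        add("type_vocabulary", "error", m$id,
            paste0("unknown ", what, " type: ", m$type))
      }
      fr <- m$fragments[[1L]]
      if (max(fr[, 2L]) > n_text || min(fr[, 1L]) < 0L) {
        add("offset_range", "error", m$id, "span offsets outside document text")
      } else if (slice_surface(doc$text, fr) != m$surface) {
        add("surface_integrity", "error", m$id,
            "stored surface does not match text slice")
      }
    }
  }
  check_mentions(doc$entities, schema$entity_types, "entity")
  check_mentions(doc$triggers, schema$relation_types, "trigger")

  known <- c(doc$entities$id, doc$triggers$id)
  for (i in seq_len(nrow(doc$relations))) {
    r <- doc$relations[i, ]
    if (!r$type %in% schema$relation_types) {
      add("type_vocabulary", "error", r$id,
          paste0("unknown relation type: ", r$type))
      next
    }
    sig <- relation_signature(r$type, schema)
    n_themes <- sum(!is.na(c(r$theme1, r$theme2)))
    if (sig == "symmetric") {
      if (!is.na(r$agent)) {
        add("argument_signature", "error", r$id,
            "symmetric relation has agent")
      }
      if (n_themes != 2L) {
        add("argument_signature", "error", r$id,
            sprintf("symmetric relation needs 2 themes, has %d", n_themes))
      }
    } else {
      if (is.na(r$agent) || n_themes != 1L) {
        add("argument_signature", "error", r$id,
            sprintf("directional relation needs 1 agent and 1 theme (agent %s, %d themes)",
                    if (is.na(r$agent)) "missing" else "present", n_themes))
      }
    }
    if (!is.na(r$certainty) && !r$certainty %in% schema$certainty_fine) {
      add("certainty_vocabulary", "error", r$id,
          paste0("unknown certainty level: ", r$certainty))
    }
    refs <- c(r$agent, r$theme1, r$theme2)
    dang <- setdiff(refs[!is.na(refs)], doc$entities$id)
    if (length(dang)) {
      add("reference_integrity", "error", r$id,
          paste0("argument(s) not entity mentions: ", paste(dang, collapse = ", ")))
    }
    if (!is.na(r$trigger) && !r$trigger %in% doc$triggers$id) {
      add("reference_integrity", "error", r$id,
          paste0("trigger reference unknown: ", r$trigger))
    }
  }

  depths <- nesting_depths(doc$entities)
  too_deep <- which(depths > max_depth)
  for (i in too_deep) {
    add("nesting_depth", "warning", doc$entities$id[i],
        sprintf("mention nested at depth %d (> %d)", depths[i], max_depth))
  }

  if (length(v)) bind_rows(v) else
    tibble(rule = character(), severity = character(),
           id = character(), message = character())
}

# Depth of each entity mention in the containment partial order: 1 for a
# top-level mention, 2 for a mention strictly inside another, etc.
# Containment is on envelopes (min start, max end).
nesting_depths <- function(entities) {
  n <- nrow(entities)
  if (n == 0L) return(integer())
  env <- t(vapply(entities$fragments, span_envelope, integer(2L)))
  depth <- rep(1L, n)
  contains <- function(a, b) { # a strictly contains b
    env[a, 1L] <= env[b, 1L] && env[a, 2L] >= env[b, 2L] &&
      (env[a, 2L] - env[a, 1L]) > (env[b, 2L] - env[b, 1L])
  }
  for (rep_i in seq_len(n)) {
    changed <- FALSE
    for (b in seq_len(n)) {
      parents <- Filter(function(a) a != b && contains(a, b), seq_len(n))
      if (length(parents)) {
        d <- max(depth[parents]) + 1L
        if (d > depth[b]) { depth[b] <- d; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  depth
}

# ---- corpus I/O -------------------------------------------------------------

#' Read a standoff corpus directory
#'
#' Expects `<doc_id>.txt` / `<doc_id>.ann` pairs and an optional
#' `manifest.json` listing `doc_id`, `section` and `split` per document.
#'
#' @param dir Directory path.
#' @param schema An [default_schema()] object.
#' @return A list of [standoff_document()]s, with the manifest (a tibble)
#'   attached as attribute `"manifest"` when present.
#' @export
read_corpus <- function(dir, schema = default_schema()) {
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- NULL
  if (file.exists(manifest_path)) {
    manifest <- as_tibble(jsonlite::fromJSON(manifest_path))
  }
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(tp) {
    doc_id <- sub("\\.txt$", "", basename(tp))
    ap <- file.path(dir, paste0(doc_id, ".ann"))
    ann <- if (file.exists(ap)) paste(readLines(ap, warn = FALSE), collapse = "\n") else ""
    section <- "title_abstract"
    if (!is.null(manifest) && doc_id %in% manifest$doc_id) {
      section <- manifest$section[match(doc_id, manifest$doc_id)]
    }
    parse_standoff(paste(readLines(tp, warn = FALSE), collapse = "\n"),
                   ann, schema, doc_id = doc_id, section = section)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  attr(docs, "manifest") <- manifest
  docs
}

#' Write a corpus to a standoff directory
#'
#' @param corpus List of [standoff_document()]s.
#' @param dir Output directory (created if needed).
#' @param manifest Optional manifest tibble (`doc_id`, `section`, `split`).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    out <- write_standoff(doc)
    writeLines(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")), useBytes = TRUE)
    writeLines(out$ann, file.path(dir, paste0(doc$doc_id, ".ann")), useBytes = TRUE)
  }
  if (is.null(manifest)) {
    manifest <- tibble(
      doc_id = vapply(corpus, `[[`, "", "doc_id"),
      section = vapply(corpus, `[[`, "", "section"),
      split = NA_character_
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(dir)
}

# ---- tidy accessors ---------------------------------------------------------

#' Corpus-level annotation tables
#'
#' Flatten a corpus (list of documents) into tidy tibbles keyed by
#' `doc_id`.  Fragment lists are preserved as list-columns; `start` and
#' `end` give the envelope.
#'
#' @param corpus List of [standoff_document()]s.
#' @return A tibble.
#' @export
entity_table <- function(corpus) mention_table(corpus, "entities")

#' @rdname entity_table
#' @export
trigger_table <- function(corpus) mention_table(corpus, "triggers")

mention_table <- function(corpus, what) {
  rows <- lapply(corpus, function(d) {
    tb <- d[[what]]
    if (nrow(tb) == 0L) return(NULL)
    tb$doc_id <- d$doc_id
    tb$section <- d$section
    env <- t(vapply(tb$fragments, span_envelope, integer(2L)))
    tb$start <- env[, 1L]; tb$end <- env[, 2L]
    tb$n_fragments <- vapply(tb$fragments, nrow, 1L)
    tb
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(doc_id = character(), section = character(), id = character(),
                  type = character(), fragments = list(), surface = character(),
                  start = integer(), end = integer(), n_fragments = integer()))
  }
  select(out, "doc_id", "section", "id", "type", "fragments", "surface",
         "start", "end", "n_fragments")
}

#' @rdname entity_table
#' @export
relation_table <- function(corpus) {
  rows <- lapply(corpus, function(d) {
    tb <- d$relations
    if (nrow(tb) == 0L) return(NULL)
    tb$doc_id <- d$doc_id
    tb$section <- d$section
    tb
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- empty_relations()
    out$doc_id <- character(); out$section <- character()
  }
  select(out, "doc_id", "section", "id", "type", "agent", "theme1", "theme2",
         "trigger", "certainty", "sentence_bound")
}
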