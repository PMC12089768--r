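# Descriptive corpus statistics.

#' Descriptive statistics of a standoff corpus
#'
#' Computes the summary table a corpus paper would print: document,
#' sentence, word, entity, trigger and relation counts (totals and
#' per-document medians, split by section), per-type entity and relation
#' distributions, the relation/trigger ratio per relation type, the
#' percentages of discontinuous, nested and cross-sentence annotations,
#' and the distribution of certainty levels (including the share of each
#' fine level among relations stated with uncertainty).
#'
#' Documents are segmented on the fly when sentence boundaries are
#' missing.  Cross-sentence rates are computed before any sentence-bound
#' filtering, from the `sentence_bound` flag.
#'
#' @param corpus List of [standoff_document()]s.
#' @param schema An [default_schema()] object.
#' @return An object of class `corpus_stats`: a list of tibbles
#'   (`totals`, `entity_types`, `relation_types`, `rates`, `certainty`).
#' @export
corpus_statistics <- function(corpus, schema = default_schema()) {
  corpus <- lapply(corpus, function(d) {
    if (is.null(d$sentences) && nchar(d$text) > 0L) d <- segment_sentences(d)
    if (!is.null(d$sentences) && nrow(d$relations) > 0L &&
        anyNA(d$relations$sentence_bound)) {
      d <- filter_sentence_bound(d, drop = FALSE)
    }
    d
  })
  sections <- vapply(corpus, `[[`, "", "section")

  per_doc_proto <- tibble(
    doc_id = character(), section = character(), sentences = integer(),
    words = integer(), entities = integer(), triggers = integer(),
    relations = integer())
  per_doc <- dplyr::bind_rows(c(
    list(per_doc_proto),
    unname(lapply(corpus, function(d) {
      tibble(
        doc_id = d$doc_id, section = d$section,
        sentences = if (is.null(d$sentences)) 0L else nrow(d$sentences),
        words = nrow(tokenize_words(d$text)),
        entities = nrow(d$entities), triggers = nrow(d$triggers),
        relations = nrow(d$relations)
      )
    }))))

  section_totals <- function(tb) {
    tb %>%
      group_by(.data$section) %>%
      summarise(
        documents = dplyr::n(),
        dplyr::across(c("sentences", "words", "entities", "triggers", "relations"),
                      list(total = sum, median = ~ stats::median(.x))),
        .groups = "drop"
      )
  }
  totals <- if (nrow(per_doc)) section_totals(per_doc) else
    tibble(section = character())
  grand <- tibble(
    section = "total",
    documents = length(unique(per_doc$doc_id)),
    sentences_total = sum(per_doc$sentences), sentences_median = stats::median(per_doc$sentences),
    words_total = sum(per_doc$words), words_median = stats::median(per_doc$words),
    entities_total = sum(per_doc$entities), entities_median = stats::median(per_doc$entities),
    triggers_total = sum(per_doc$triggers), triggers_median = stats::median(per_doc$triggers),
    relations_total = sum(per_doc$relations), relations_median = stats::median(per_doc$relations)
  )
  if (nrow(per_doc) == 0L) grand$documents <- 0L
  totals <- bind_rows(totals, grand)

  ents <- entity_table(corpus)
  trgs <- trigger_table(corpus)
  rels <- relation_table(corpus)

  entity_types <- tibble(type = schema$entity_types) %>%
    left_join(ents %>% dplyr::count(.data$type), by = "type") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           share_pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)

  relation_types <- tibble(type = schema$relation_types) %>%
    left_join(rels %>% dplyr::count(.data$type, name = "n_relations"), by = "type") %>%
    left_join(trgs %>% dplyr::count(.data$type, name = "n_triggers"), by = "type") %>%
    mutate(
      n_relations = dplyr::coalesce(.data$n_relations, 0L),
      n_triggers = dplyr::coalesce(.data$n_triggers, 0L),
      share_pct = if (sum(.data$n_relations) > 0)
        100 * .data$n_relations / sum(.data$n_relations) else 0,
      trigger_ratio = ifelse(.data$n_triggers > 0,
                             .data$n_relations / .data$n_triggers, NA_real_)
    )

  n_ment <- nrow(ents)
  n_disc <- if (n_ment) sum(ents$n_fragments > 1L) else 0L
  n_nested <- sum(vapply(corpus, function(d) {
    sum(nesting_depths(d$entities) > 1L)
  }, integer(1L)))
  n_rel <- nrow(rels)
  n_cross <- if (n_rel) sum(!rels$sentence_bound, na.rm = TRUE) else 0L
  rates <- tibble(
    measure = c("discontinuous_mentions", "nested_mentions", "cross_sentence_relations"),
    n = c(n_disc, n_nested, n_cross),
    denominator = c(n_ment, n_ment, n_rel),
    pct = 100 * c(
      if (n_ment) n_disc / n_ment else 0,
      if (n_ment) n_nested / n_ment else 0,
      if (n_rel) n_cross / n_rel else 0
    )
  )

  certainty <- tibble(level = schema$certainty_fine) %>%
    left_join(rels %>% dplyr::count(.data$certainty, name = "n"),
              by = c(level = "certainty")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           coarse = unname(schema$certainty_map[.data$level]),
           share_pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
  unc <- certainty %>% filter(.data$coarse == "Uncertain")
  certainty <- certainty %>%
    mutate(share_among_uncertain_pct = ifelse(
      .data$coarse == "Uncertain" & sum(unc$n) > 0,
      100 * .data$n / sum(unc$n), NA_real_))

  structure(
    list(totals = totals, entity_types = entity_types,
         relation_types = relation_types, rates = rates,
         certainty = certainty),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats>\n\nTotals by section:\n")
  print(as.data.frame(x$totals), row.names = FALSE)
  cat("\nRates (%):\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  cat("\nTop entity types:\n")
  print(as.data.frame(utils::head(dplyr::arrange(x$entity_types,
                                                 dplyr::desc(.data$n)), 5L)),
        row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy corpus statistics
#'
#' @param x A `corpus_stats` object.
#' @param ... Unused.
#' @return A long tibble with one row per reported statistic.
#' @export
tidy.corpus_stats <- function(x, ...) {
  bind_rows(
    x$totals %>%
      tidyr::pivot_longer(-"section", names_to = "statistic") %>%
      mutate(table = "totals", .before = 1L),
    x$rates %>%
      select(section = "measure", value = "pct") %>%
      mutate(table = "rates", statistic = "pct", .before = 1L)
  )
}

#' Plot the entity and relation type distributions
#'
#' @param x A `corpus_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corpus_stats <- function(x, ...) {
  df <- bind_rows(
    x$entity_types %>% select("type", "n") %>% mutate(kind = "entities"),
    x$relation_types %>% select("type", n = "n_relations") %>% mutate(kind = "relations")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$type, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = NULL, y = "mentions / relations")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
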