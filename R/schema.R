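#' Annotation schema for diet-microbiome corpora
#'
#' The schema fixes the entity vocabulary (15 types), the relation
#' vocabulary (13 types) together with each type's argument signature
#' (directional Agent/Theme vs symmetric two-Theme), the fine-grained
#' six-level certainty vocabulary, the coarse three-level vocabulary and
#' the total fine-to-coarse map.
#'
#' @return An object of class `annotation_schema`: a list with elements
#'   `entity_types`, `relation_types`, `symmetric_types`,
#'   `directional_types`, `certainty_fine`, `certainty_coarse` and
#'   `certainty_map` (a named character vector mapping fine to coarse).
#' @examples
#' sch <- default_schema()
#' sch$entity_types
#' sch$certainty_map[["Possible"]]
#' @export
default_schema <- function() {
  entity_types <- c(
    "Food", "Nutrient", "DietPattern", "Microorganism", "DiversityMetric",
    "Metabolite", "Physiology", "Disease", "Measurement", "Enzyme",
    "Gene", "Chemical", "Methodology", "Population", "Biospecimen"
  )
  relation_types <- c(
    "affects", "improves", "worsens", "associated_with",
    "pos_associated_with", "neg_associated_with", "interacts_with",
    "increases", "decreases", "causes", "prevents", "predisposes",
    "has_component"
  )
  symmetric_types <- c("associated_with", "interacts_with")
  certainty_fine <- c("Factual", "Probable", "Possible", "Doubtful",
                      "Negated", "Unknown")
  certainty_coarse <- c("Factual", "Negated", "Uncertain")
  certainty_map <- c(
    Factual = "Factual", Negated = "Negated",
    Probable = "Uncertain", Possible = "Uncertain",
    Doubtful = "Uncertain", Unknown = "Uncertain"
  )
  structure(
    list(
      entity_types = entity_types,
      relation_types = relation_types,
      symmetric_types = symmetric_types,
      directional_types = setdiff(relation_types, symmetric_types),
      certainty_fine = certainty_fine,
      certainty_coarse = certainty_coarse,
      certainty_map = certainty_map
    ),
    class = "annotation_schema"
  )
}

#' @export
print.annotation_schema <- function(x, ...) {
  cat("<annotation_schema>\n")
  cat("  entity types:  ", length(x$entity_types), "\n")
  cat("  relation types:", length(x$relation_types),
      "(", length(x$symmetric_types), "symmetric )\n")
  cat("  certainty:     ", paste(x$certainty_fine, collapse = ", "),
      "->", paste(x$certainty_coarse, collapse = "/"), "\n")
  invisible(x)
}

#' Coarsen fine-grained certainty levels
#'
#' Maps the six-level certainty vocabulary onto the three-level one used
#' for factuality classification: Factual stays Factual, Negated stays
#' Negated, and Probable, Possible, Doubtful and Unknown collapse to
#' Uncertain.
#'
#' @param fine Character vector of fine-grained certainty levels.
#' @param schema An [default_schema()] object.
#' @return Character vector of coarse levels, same length as `fine`.
#' @examples
#' map_certainty(c("Possible", "Factual", "Negated"))
#' @export
map_certainty <- function(fine, schema = default_schema()) {
  bad <- setdiff(unique(fine), names(schema$certainty_map))
  if (length(bad) > 0) {
    stop("unknown certainty level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(schema$certainty_map[fine])
}

# Argument signature for a relation type: "directional" (one Agent, one
# Theme) or "symmetric" (two Themes, no Agent).
relation_signature <- function(type, schema = default_schema()) {
  ifelse(type %in% schema$symmetric_types, "symmetric", "directional")
}
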