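# The loaded-ontology container: axioms in deterministic order plus an
# entity index (IRI, kind, optional rdfs:label) and the prefix map used
# for CURIE rendering.

new_axiom_set <- function(axioms, entities, prefixes, source_format,
                          unsupported = integer()) {
  structure(
    list(
      axioms = axioms,
      entities = entities,
      prefixes = prefixes,
      source_format = source_format,
      unsupported = unsupported
    ),
    class = "owl_axiom_set"
  )
}

# Assemble an axiom set from raw reader output.
#
# labels: named character vector, IRI -> label (multiple values allowed;
# conflict resolved deterministically: lexicographically smallest English-
# tagged label, else lexicographically smallest overall).
# declared: tibble(iri, kind) from explicit declarations; reference-implied
# kinds fill in anything undeclared.
build_axiom_set <- function(axioms, labels = character(), declared = NULL,
                            prefixes = character(), source_format = "memory",
                            unsupported = integer(), quiet = TRUE) {
  prefixes <- c(prefixes[!names(prefixes) %in% names(BASE_PREFIXES)], BASE_PREFIXES)

  # deduplicate by logical identity, then sort by (type, Manchester rendering)
  keys <- vapply(axioms, axiom_key, "")
  axioms <- axioms[!duplicated(keys)]

  # entity index: declarations win over kinds implied by reference positions
  ref_rows <- unlist(lapply(axioms, axiom_refs), recursive = FALSE)
  refs <- if (length(ref_rows)) {
    tibble::tibble(
      iri = vapply(ref_rows, `[[`, "", "iri"),
      kind = vapply(ref_rows, `[[`, "", "kind")
    )
  } else {
    tibble::tibble(iri = character(), kind = character())
  }
  declared <- declared %||% tibble::tibble(iri = character(), kind = character())
  entities <- dplyr::bind_rows(declared, refs)
  entities <- dplyr::distinct(entities, .data$iri, .keep_all = TRUE)
  entities <- dplyr::filter(entities, !startsWith(.data$iri, XSD_NS) | .data$kind == "datatype")

  entities$label <- vapply(entities$iri, function(iri) {
    pick_label(labels[names(labels) == iri], iri, quiet = quiet)
  }, "", USE.NAMES = FALSE)
  entities$label[entities$label == ""] <- NA_character_
  entities <- dplyr::arrange(entities, .data$iri)

  axset <- new_axiom_set(axioms, entities, prefixes, source_format, unsupported)
  ord <- order(
    vapply(axioms, `[[`, "", "type"),
    vapply(axioms, function(a) render_manchester(a, axset = axset), ""),
    method = "radix"
  )
  axset$axioms <- axioms[ord]
  axset
}

# deterministic label choice when several rdfs:label values exist
pick_label <- function(values, iri, quiet = TRUE) {
  if (length(values) == 0L) return("")
  values <- unique(as.character(values))
  if (length(values) > 1L && !quiet) {
    message("multiple rdfs:label values for <", iri, ">; using the ",
            "lexicographically smallest")
  }
  sort(values, method = "radix")[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.owl_axiom_set <- function(x, ...) {
  cat("<owl_axiom_set> ", length(x$axioms), " axioms, ",
      nrow(x$entities), " entities (source: ", x$source_format, ")\n", sep = "")
  if (length(x$unsupported)) {
    cat("  unsupported axioms skipped: ",
        paste0(names(x$unsupported), " (", x$unsupported, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Count axioms by type
#'
#' Tallies the supported axioms in a loaded ontology by axiom type, the
#' per-type "n" that accompanies per-type rating summaries.
#'
#' @param axset An `owl_axiom_set` from [load_ontology()].
#' @return A tibble with columns `axiom_type` and `n`; only types present
#'   appear, and the counts sum to the total number of axioms.
#' @export
#' @examples
#' path <- write_paper_examples(tempdir())["turtle"]
#' count_by_type(load_ontology(path))
count_by_type <- function(axset) {
  stopifnot(inherits(axset, "owl_axiom_set"))
  types <- vapply(axset$axioms, `[[`, "", "type")
  if (length(types) == 0L) {
    return(tibble::tibble(axiom_type = character(), n = integer()))
  }
  tab <- table(types)
  tibble::tibble(axiom_type = names(tab), n = as.integer(tab))
}

#' Entity table of a loaded ontology
#'
#' @param axset An `owl_axiom_set`.
#' @return A tibble with columns `iri`, `kind`
#'   (class/object_property/data_property/named_individual/datatype) and
#'   `label` (`NA` when the loaded closure carries no rdfs:label).
#' @export
entity_table <- function(axset) {
  stopifnot(inherits(axset, "owl_axiom_set"))
  tibble::as_tibble(axset$entities)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an axiom set into one row per axiom
#'
#' @param x An `owl_axiom_set`.
#' @param ... Unused.
#' @return A tibble with `axiom_type` and `manchester` columns.
#' @method tidy owl_axiom_set
#' @export
tidy.owl_axiom_set <- function(x, ...) {
  tibble::tibble(
    axiom_type = vapply(x$axioms, `[[`, "", "type"),
    manchester = vapply(x$axioms, function(a) render_manchester(a, axset = x), "")
  )
}

#' One-row overview of an axiom set
#'
#' @param x An `owl_axiom_set`.
#' @param ... Unused.
#' @return A one-row tibble: axiom, entity and unlabeled-entity counts plus
#'   the number of unsupported axioms skipped at load.
#' @method glance owl_axiom_set
#' @export
glance.owl_axiom_set <- function(x, ...) {
  tibble::tibble(
    n_axioms = length(x$axioms),
    n_entities = nrow(x$entities),
    n_unlabeled = sum(is.na(x$entities$label)),
    n_unsupported = sum(x$unsupported)
  )
}
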