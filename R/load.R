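# load_ontology(): one entry point over the four supported serializations.

FORMATS <- c("rdfxml", "turtle", "owlxml", "functional")

detect_format <- function(path, text) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ttl", "n3")) return("turtle")
  if (ext %in% c("ofn", "fss")) return("functional")
  if (ext == "owx") return("owlxml")
  head <- substr(text, 1L, 4000L)
  if (grepl("<rdf:RDF|xmlns:rdf\\s*=", head)) return("rdfxml")
  if (grepl("<(\\w+:)?Ontology[\\s>]", head, perl = TRUE) && grepl("<\\?xml|<Ontology", head)) {
    return("owlxml")
  }
  if (grepl("^\\s*(Prefix\\s*\\(|Ontology\\s*\\()", head)) return("functional")
  if (grepl("@prefix|@base|^PREFIX", head)) return("turtle")
  if (grepl("^\\s*<\\?xml", head)) return("rdfxml")
  "turtle"
}

#' Load an OWL 2 ontology into the axiom model
#'
#' Reads an ontology from RDF/XML, Turtle, OWL/XML or OWL functional syntax
#' and returns the axioms of the 14 supported types (see
#' [owl_supported_types()]) together with an entity index carrying each
#' entity's `rdfs:label`, when one exists in the loaded file. Axioms of other
#' types are counted in the result's `unsupported` field and skipped; no
#' label is ever invented for an entity the file does not label, so
#' downstream sentences fall back to IRI-fragment wording for terms whose
#' defining ontology was not imported.
#'
#' Imports are not resolved by default. With `follow_imports = TRUE`,
#' `owl:imports` targets that name a local file (absolute, or relative to
#' the ontology's directory) are loaded and merged; remote IRIs are never
#' fetched.
#'
#' @param path Path to the ontology file.
#' @param format One of `"rdfxml"`, `"turtle"`, `"owlxml"`, `"functional"`;
#'   detected from the extension and content when omitted.
#' @param follow_imports Follow `owl:imports` pointing at local files.
#' @param quiet Suppress the load summary message.
#' @return An `owl_axiom_set`: axioms in deterministic order (axiom type,
#'   then Manchester rendering), an entity table, the prefix map, and counts
#'   of unsupported axioms.
#' @export
#' @examples
#' path <- write_paper_examples(tempdir())["turtle"]
#' ont <- load_ontology(path)
#' count_by_type(ont)
load_ontology <- function(path, format = NULL, follow_imports = FALSE,
                          quiet = TRUE) {
  if (!file.exists(path) || dir.exists(path)) {
    stop("cannot read ontology file: ", path, call. = FALSE)
  }
  text <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  format <- format %||% detect_format(path, text)
  format <- match.arg(format, FORMATS)

  model <- tryCatch(
    switch(format,
      turtle = {
        res <- parse_turtle(text)
        m <- triples_to_model(res$triples)
        m$prefixes <- res$prefixes
        m$triples <- res$triples
        m
      },
      rdfxml = {
        res <- parse_rdfxml(xml2::read_xml(text))
        m <- triples_to_model(res$triples)
        m$prefixes <- res$prefixes
        m$triples <- res$triples
        m
      },
      owlxml = parse_owlxml(xml2::read_xml(text)),
      functional = parse_functional(text)
    ),
    error = function(e) {
      stop("failed to parse '", path, "' as ", format, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )

  if (follow_imports) {
    for (target in import_targets(model)) {
      local <- resolve_local_import(target, dirname(path))
      if (is.na(local)) next
      sub <- load_ontology(local, follow_imports = TRUE, quiet = TRUE)
      model$axioms <- c(model$axioms, sub$axioms)
      sub_lab <- stats::setNames(sub$entities$label, sub$entities$iri)
      sub_lab <- sub_lab[!is.na(sub_lab)]
      model$labels <- c(model$labels, sub_lab)
      model$declared <- dplyr::bind_rows(
        model$declared, sub$entities[, c("iri", "kind")])
    }
  }

  axset <- build_axiom_set(
    axioms = model$axioms, labels = model$labels, declared = model$declared,
    prefixes = model$prefixes, source_format = format,
    unsupported = model$unsupported, quiet = quiet
  )
  if (!quiet) {
    message("loaded ", length(axset$axioms), " supported axioms (",
            sum(axset$unsupported), " unsupported skipped), ",
            nrow(axset$entities), " entities, ",
            sum(is.na(axset$entities$label)), " unlabeled")
  }
  axset
}

import_targets <- function(model) {
  if (!is.null(model$triples)) {
    tr <- model$triples
    return(tr$o[tr$p == owl_iri("imports") & tr$o_kind == "iri"])
  }
  character()
}

resolve_local_import <- function(target, dir) {
  candidates <- c(target, sub("^file://", "", target), file.path(dir, basename(target)))
  for (cand in candidates) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  NA_character_
}
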