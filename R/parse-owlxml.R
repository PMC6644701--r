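# OWL/XML reader: the OWL 2 XML serialization maps almost one-to-one onto
# the functional-style form tree, so each element becomes a form and the
# shared forms_to_model() back end does the rest.

parse_owlxml <- function(doc) {
  root <- xml2::xml_root(doc)
  prefixes <- character()
  kids <- xml2::xml_children(root)

  for (el in kids) {
    if (xml2::xml_name(el) == "Prefix") {
      nm <- xml2::xml_attr(el, "name")
      iri <- xml2::xml_attr(el, "IRI")
      if (!is.na(nm) && nzchar(nm) && !is.na(iri)) prefixes[[nm]] <- iri
    }
  }
  all_prefixes <- c(prefixes, BASE_PREFIXES)

  resolve_iri <- function(el) {
    iri <- xml2::xml_attr(el, "IRI")
    if (!is.na(iri)) return(iri)
    ab <- xml2::xml_attr(el, "abbreviatedIRI")
    if (!is.na(ab)) {
      colon <- regexpr(":", ab, fixed = TRUE)
      pfx <- substr(ab, 1L, colon - 1L)
      if (!pfx %in% names(all_prefixes)) {
        stop("OWL/XML: undeclared prefix '", pfx, ":'", call. = FALSE)
      }
      return(paste0(all_prefixes[[pfx]], substr(ab, colon + 1L, nchar(ab))))
    }
    stop("OWL/XML: entity element without IRI", call. = FALSE)
  }

  to_form <- function(el) {
    nm <- xml2::xml_name(el)
    if (nm == "Literal") {
      dt <- xml2::xml_attr(el, "datatypeIRI")
      dt <- if (is.na(dt)) {
        xsd_iri("string")
      } else if (startsWith(dt, "&xsd;")) {
        paste0(XSD_NS, substr(dt, 6L, nchar(dt)))
      } else dt
      return(owl_literal(xml2::xml_text(el), dt))
    }
    if (nm %in% c(names(DECL_KINDS), "AnnotationProperty")) {
      return(list(op = nm, iri = resolve_iri(el)))
    }
    if (nm %in% c("IRI", "AbbreviatedIRI")) {
      txt <- xml2::xml_text(el)
      if (nm == "AbbreviatedIRI") {
        colon <- regexpr(":", txt, fixed = TRUE)
        pfx <- substr(txt, 1L, colon - 1L)
        txt <- paste0(all_prefixes[[pfx]], substr(txt, colon + 1L, nchar(txt)))
      }
      return(list(op = "IRI", iri = txt))
    }
    list(op = nm, args = lapply(xml2::xml_children(el), to_form))
  }

  forms <- lapply(kids[xml2::xml_name(kids) != "Prefix"], to_form)
  model <- forms_to_model(forms)
  model$prefixes <- prefixes
  model
}
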