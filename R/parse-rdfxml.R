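# RDF/XML reader over xml2, producing the shared triple table. Handles the
# node/property element striping RDF/XML uses: rdf:Description and typed node
# elements, rdf:about / rdf:resource / rdf:nodeID, nested node elements,
# rdf:parseType="Collection"/"Resource", datatyped and plain literals.

parse_rdfxml <- function(doc) {
  ns <- xml2::xml_ns(doc)
  nsmap <- as.list(ns)

  expand_qname <- function(qn) {
    colon <- regexpr(":", qn, fixed = TRUE)
    if (colon == -1L) stop("RDF/XML: unqualified name '", qn, "'", call. = FALSE)
    pfx <- substr(qn, 1L, colon - 1L)
    local <- substr(qn, colon + 1L, nchar(qn))
    uri <- nsmap[[pfx]]
    if (is.null(uri)) stop("RDF/XML: unknown namespace prefix '", pfx, "'", call. = FALSE)
    paste0(uri, local)
  }

  rows <- list()
  emit <- function(s, p, o, o_kind, dtype = NA_character_, lang = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, o_kind = o_kind,
                                       dtype = dtype, lang = lang)
  }
  bn <- 0L
  fresh_bnode <- function() { bn <<- bn + 1L; paste0("_:xb", bn) }

  rdf_attr <- function(attrs, what) {
    key <- paste0("rdf:", what)
    if (key %in% names(attrs)) attrs[[key]] else NA_character_
  }

  node_element <- function(el) {
    qn <- xml2::xml_name(el, ns)
    attrs <- xml2::xml_attrs(el, ns)
    subj <- rdf_attr(attrs, "about")
    if (is.na(subj)) {
      nid <- rdf_attr(attrs, "nodeID")
      subj <- if (!is.na(nid)) paste0("_:", nid) else fresh_bnode()
    }
    full <- expand_qname(qn)
    if (full != rdf_iri("Description")) emit(subj, rdf_iri("type"), full, "iri")
    # property attributes (non-rdf, non-xmlns) are literal shorthands
    for (an in names(attrs)) {
      if (startsWith(an, "rdf:") || startsWith(an, "xmlns") ||
          startsWith(an, "xml:") || !grepl(":", an, fixed = TRUE)) next
      emit(subj, expand_qname(an), attrs[[an]], "literal", xsd_iri("string"))
    }
    for (child in xml2::xml_children(el)) property_element(child, subj)
    subj
  }

  property_element <- function(el, subj) {
    p <- expand_qname(xml2::xml_name(el, ns))
    attrs <- xml2::xml_attrs(el, ns)
    res <- rdf_attr(attrs, "resource")
    if (!is.na(res)) { emit(subj, p, res, "iri"); return(invisible()) }
    nid <- rdf_attr(attrs, "nodeID")
    if (!is.na(nid)) { emit(subj, p, paste0("_:", nid), "bnode"); return(invisible()) }
    ptype <- rdf_attr(attrs, "parseType")
    if (identical(ptype, "Collection")) {
      items <- vapply(xml2::xml_children(el), node_element, "")
      if (length(items) == 0L) { emit(subj, p, rdf_iri("nil"), "iri"); return(invisible()) }
      nodes <- vapply(items, function(x) fresh_bnode(), "")
      emit(subj, p, nodes[[1L]], "bnode")
      for (j in seq_along(items)) {
        emit(nodes[[j]], rdf_iri("first"), items[[j]],
             if (is_bnode(items[[j]])) "bnode" else "iri")
        nxt <- if (j < length(items)) nodes[[j + 1L]] else rdf_iri("nil")
        emit(nodes[[j]], rdf_iri("rest"), nxt, if (j < length(items)) "bnode" else "iri")
      }
      return(invisible())
    }
    if (identical(ptype, "Resource")) {
      node <- fresh_bnode()
      emit(subj, p, node, "bnode")
      for (child in xml2::xml_children(el)) property_element(child, node)
      return(invisible())
    }
    kids <- xml2::xml_children(el)
    if (length(kids) > 0L) {
      o <- node_element(kids[[1L]])
      emit(subj, p, o, if (is_bnode(o)) "bnode" else "iri")
      return(invisible())
    }
    dt <- rdf_attr(attrs, "datatype")
    lang <- if ("xml:lang" %in% names(attrs)) attrs[["xml:lang"]] else NA_character_
    emit(subj, p, xml2::xml_text(el), "literal",
         if (is.na(dt)) xsd_iri("string") else dt, lang)
    invisible()
  }

  root <- xml2::xml_root(doc)
  root_name <- expand_qname(xml2::xml_name(root, ns))
  if (root_name == rdf_iri("RDF")) {
    for (child in xml2::xml_children(root)) node_element(child)
  } else {
    node_element(root)
  }

  tr <- if (length(rows)) {
    tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
      data.frame(s = r$s, p = r$p, o = r$o, o_kind = r$o_kind,
                 dtype = r$dtype, lang = r$lang, stringsAsFactors = FALSE)
    })))
  } else new_triples()

  prefixes <- unlist(nsmap)
  keep <- grepl("^[A-Za-z][A-Za-z0-9_-]*$", names(prefixes))
  list(triples = tr, prefixes = prefixes[keep])
}
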