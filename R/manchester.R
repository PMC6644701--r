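# Manchester syntax: a one-line rendering per axiom (the CSV's logic
# column) and a recursive-descent parser for the supported subset, used to
# verify that every rendering re-parses to a logically identical axiom.

# ---- names ------------------------------------------------------------------

# CURIE for an IRI: declared prefixes first (longest namespace match), then
# the OBO PURL convention (.../obo/ICO_0000062 -> ICO:0000062), else <iri>.
curie_of <- function(iri, prefixes = BASE_PREFIXES) {
  best <- ""
  best_pfx <- NA_character_
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (nzchar(ns) && startsWith(iri, ns) && nchar(ns) > nchar(best)) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (grepl("^[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", local)) {
        best <- ns; best_pfx <- pfx
      }
    }
  }
  if (!is.na(best_pfx)) {
    return(paste0(best_pfx, ":", substr(iri, nchar(best) + 1L, nchar(iri))))
  }
  m <- regmatches(iri, regexec("^http://purl\\.obolibrary\\.org/obo/([A-Za-z]+)_([A-Za-z0-9_]+)$", iri))[[1L]]
  if (length(m) == 3L) return(paste0(m[2L], ":", m[3L]))
  paste0("<", iri, ">")
}

m_name <- function(iri, policy, axset) {
  prefixes <- if (!is.null(axset)) axset$prefixes else BASE_PREFIXES
  if (policy == "label" && !is.null(axset)) {
    hit <- axset$entities$label[axset$entities$iri == iri]
    if (length(hit) && !is.na(hit[[1L]])) {
      lab <- hit[[1L]]
      if (grepl("[^A-Za-z0-9_]", lab)) return(paste0("'", lab, "'"))
      return(lab)
    }
  }
  curie_of(iri, prefixes)
}

m_literal <- function(lit, policy, axset) {
  dt <- lit$datatype
  if (dt %in% c(xsd_iri("integer"), xsd_iri("decimal"), xsd_iri("double"),
                xsd_iri("boolean"))) {
    return(lit$value)
  }
  if (dt == xsd_iri("string")) return(paste0("\"", lit$value, "\""))
  paste0("\"", lit$value, "\"^^", m_name(dt, "curie", axset))
}

m_expr <- function(expr, policy, axset) {
  atom <- function(x) {
    if (inherits(x, "owl_datatype")) return(m_name(x$iri, policy, axset))
    if (is_literal(x)) return(m_literal(x, policy, axset))
    if (is.character(x)) return(m_name(x, policy, axset))
    if (x$kind == "named") m_name(x$iri, policy, axset)
    else if (x$kind == "other") x$manchester
    else paste0("(", m_expr(x, policy, axset), ")")
  }
  switch(expr$kind,
    named = m_name(expr$iri, policy, axset),
    intersection = paste(vapply(expr$children, atom, ""), collapse = " and "),
    union = paste(vapply(expr$children, atom, ""), collapse = " or "),
    complement = paste("not", atom(expr$children[[1L]])),
    some_values = paste(m_name(expr$property, policy, axset), "some", atom(expr$filler)),
    all_values = paste(m_name(expr$property, policy, axset), "only", atom(expr$filler)),
    has_value = paste(m_name(expr$property, policy, axset), "value", atom(expr$filler)),
    other = expr$manchester
  )
}

#' Render an axiom in Manchester syntax
#'
#' One-line Manchester rendering with the W3C keywords (`SubClassOf:`,
#' `EquivalentTo:`, `DisjointWith:`, `Domain:`, `Range:`, `some`, `and`,
#' `or`, `not`, ...). Entity names follow `name_policy`: `"curie"` (default;
#' stable identifiers for CSV export) or `"label"` (human-facing sheets;
#' labels containing spaces are single-quoted, unlabeled entities fall back
#' to CURIEs). IRIs with no matching prefix render as `<iri>`.
#'
#' @param axiom An `owl_axiom`.
#' @param name_policy `"curie"` or `"label"`.
#' @param axset Optional `owl_axiom_set` supplying prefixes and labels.
#' @return A character scalar.
#' @export
#' @examples
#' a <- ax_subclass(ce_named("http://purl.obolibrary.org/obo/ICO_0000062"),
#'                  ce_named("http://purl.obolibrary.org/obo/ICO_0000073"))
#' render_manchester(a)
render_manchester <- function(axiom, name_policy = c("curie", "label"),
                              axset = NULL) {
  policy <- match.arg(name_policy)
  stopifnot(inherits(axiom, "owl_axiom"))
  nm <- function(iri) m_name(iri, policy, axset)
  ex <- function(e) m_expr(e, policy, axset)
  switch(axiom$type,
    SubClassOf = paste(ex(axiom$sub), "SubClassOf:", ex(axiom$sup)),
    EquivalentClasses = paste(
      ex(axiom$exprs[[1L]]), "EquivalentTo:",
      paste(vapply(axiom$exprs[-1L], ex, ""), collapse = ", ")),
    DisjointClasses = {
      if (length(axiom$exprs) == 2L) {
        paste(ex(axiom$exprs[[1L]]), "DisjointWith:", ex(axiom$exprs[[2L]]))
      } else {
        paste("DisjointClasses:", paste(vapply(axiom$exprs, ex, ""), collapse = ", "))
      }
    },
    ClassAssertion = paste(nm(axiom$individual), "Type:", ex(axiom$expr)),
    ObjectPropertyDomain = paste(nm(axiom$property), "Domain:", ex(axiom$expr)),
    ObjectPropertyRange = paste(nm(axiom$property), "Range:", ex(axiom$expr)),
    DataPropertyDomain = paste(nm(axiom$property), "Domain:", ex(axiom$expr)),
    DataPropertyRange = paste(nm(axiom$property), "Range:", nm(axiom$datatype)),
    SymmetricObjectProperty = paste("Symmetric:", nm(axiom$property)),
    FunctionalObjectProperty = paste("Functional:", nm(axiom$property)),
    FunctionalDataProperty = paste("Functional:", nm(axiom$property)),
    ObjectPropertyAssertion = paste(nm(axiom$a), nm(axiom$property), nm(axiom$b)),
    DataPropertyAssertion = paste(nm(axiom$a), nm(axiom$property),
                                  m_literal(axiom$value, policy, axset)),
    DifferentIndividuals = {
      if (length(axiom$individuals) == 2L) {
        paste(nm(axiom$individuals[[1L]]), "DifferentFrom:", nm(axiom$individuals[[2L]]))
      } else {
        paste("DifferentIndividuals:",
              paste(vapply(axiom$individuals, nm, ""), collapse = ", "))
      }
    }
  )
}

# ---- parser -----------------------------------------------------------------

tokenize_manchester <- function(text) {
  pats <- c(
    quoted = "^'[^']*'",
    string = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    iriref = "^<[^<>\\s]*>",
    keyword = "^[A-Za-z]+:(?![A-Za-z0-9_])",
    pname = "^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?",
    number = "^[+-]?[0-9]+(?:\\.[0-9]+)?",
    name = "^[A-Za-z][A-Za-z0-9_-]*",
    punct = "^[(),]"
  )
  tokens <- character(); types <- character()
  pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[\\s]+", rest, perl = TRUE))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m)) {
        tokens <- c(tokens, m); types <- c(types, ty)
        pos <- pos + nchar(m); hit <- TRUE
        break
      }
    }
    if (!hit) stop("Manchester tokenizer: unexpected input at: ",
                   substr(rest, 1, 30), call. = FALSE)
  }
  list(tokens = tokens, types = types)
}

#' Parse a one-line Manchester axiom rendering
#'
#' Inverse of [render_manchester()] on the supported subset; resolves CURIEs
#' through the axiom set's prefix map (plus the OBO PURL convention) and
#' quoted names through its label index. Not a general Manchester file
#' parser — it exists so renderings can be checked to re-parse to logically
#' identical axioms.
#'
#' @param text One rendered axiom.
#' @param axset The `owl_axiom_set` the rendering came from (for prefixes,
#'   labels, and property kinds).
#' @return An `owl_axiom`.
#' @export
parse_manchester <- function(text, axset) {
  tk <- tokenize_manchester(text)
  toks <- tk$tokens; types <- tk$types
  i <- 1L
  ents <- axset$entities
  label_index <- stats::setNames(ents$iri, ents$label)

  peek <- function() if (i <= length(toks)) toks[[i]] else NA_character_
  peek_type <- function() if (i <= length(toks)) types[[i]] else NA_character_
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }

  resolve_name <- function(tok, ty) {
    if (ty == "iriref") return(substr(tok, 2, nchar(tok) - 1L))
    if (ty == "quoted") {
      lab <- substr(tok, 2, nchar(tok) - 1L)
      iri <- label_index[[lab]]
      if (is.null(iri) || is.na(iri)) stop("unknown label '", lab, "'", call. = FALSE)
      return(unname(iri))
    }
    if (ty == "pname") {
      colon <- regexpr(":", tok, fixed = TRUE)
      pfx <- substr(tok, 1L, colon - 1L)
      local <- substr(tok, colon + 1L, nchar(tok))
      if (pfx %in% names(axset$prefixes)) return(paste0(axset$prefixes[[pfx]], local))
      return(paste0(OBO_NS, pfx, "_", local))
    }
    if (ty == "name") {
      # bare label (no spaces) or bare name
      iri <- label_index[[tok]]
      if (!is.null(iri) && !is.na(iri)) return(unname(iri))
      return(tok)
    }
    stop("cannot resolve name token '", tok, "'", call. = FALSE)
  }

  kind_of <- function(iri) {
    hit <- ents$kind[ents$iri == iri]
    if (length(hit)) hit[[1L]] else NA_character_
  }

  parse_literal_or_name <- function() {
    ty <- peek_type(); tok <- peek()
    if (ty == "string") {
      advance()
      return(owl_literal(unescape_turtle_string(tok)))
    }
    if (ty == "number") {
      advance()
      dt <- if (grepl("\\.", tok)) xsd_iri("decimal") else xsd_iri("integer")
      return(owl_literal(tok, dt))
    }
    resolve_name(advance(), ty)
  }

  # precedence: or < and < not < restriction
  parse_expr <- function() {
    parts <- list(parse_conj())
    while (identical(peek(), "or")) { advance(); parts[[length(parts) + 1L]] <- parse_conj() }
    if (length(parts) == 1L) parts[[1L]] else do.call(ce_or, parts)
  }
  parse_conj <- function() {
    parts <- list(parse_unary())
    while (identical(peek(), "and")) { advance(); parts[[length(parts) + 1L]] <- parse_unary() }
    if (length(parts) == 1L) parts[[1L]] else do.call(ce_and, parts)
  }
  parse_unary <- function() {
    if (identical(peek(), "not")) { advance(); return(ce_not(parse_unary())) }
    parse_restriction()
  }
  parse_restriction <- function() {
    prim <- parse_primary()
    if (identical(peek(), "some") || identical(peek(), "only") || identical(peek(), "value")) {
      kw <- advance()
      if (!identical(prim$kind, "named")) stop("restriction on a complex property", call. = FALSE)
      prop <- prim$iri
      is_data <- identical(kind_of(prop), "data_property")
      if (kw == "value") {
        ty <- peek_type()
        if (ty %in% c("string", "number")) {
          return(ce_has_value(prop, parse_literal_or_name(), data = TRUE))
        }
        return(ce_has_value(prop, resolve_name(advance(), ty), data = is_data))
      }
      filler <- parse_unary()
      if (is_data && filler$kind == "named") filler <- ce_datatype(filler$iri)
      if (kw == "some") return(ce_some(prop, filler, data = is_data))
      return(ce_only(prop, filler, data = is_data))
    }
    prim
  }
  parse_primary <- function() {
    if (identical(peek(), "(")) {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("expected ')'", call. = FALSE)
      advance()
      return(e)
    }
    ty <- peek_type()
    ce_named(resolve_name(advance(), ty))
  }

  named_iri <- function(e) {
    if (!identical(e$kind, "named")) stop("expected a named entity", call. = FALSE)
    e$iri
  }

  # n-ary frame keywords first
  if (peek_type() == "keyword") {
    kw <- advance()
    if (kw == "DisjointClasses:") {
      exprs <- list(parse_expr())
      while (identical(peek(), ",")) { advance(); exprs[[length(exprs) + 1L]] <- parse_expr() }
      return(ax_disjoint(exprs))
    }
    if (kw == "DifferentIndividuals:") {
      take_name <- function() {
        ty <- peek_type()
        resolve_name(advance(), ty)
      }
      inds <- take_name()
      while (identical(peek(), ",")) {
        advance(); inds <- c(inds, take_name())
      }
      return(ax_different(sort(inds)))
    }
    if (kw == "Symmetric:") return(ax_symmetric(named_iri(parse_primary())))
    if (kw == "Functional:") {
      prop <- named_iri(parse_primary())
      if (identical(kind_of(prop), "data_property")) return(ax_functional_data(prop))
      return(ax_functional_obj(prop))
    }
    stop("unexpected leading keyword ", kw, call. = FALSE)
  }

  lhs <- parse_expr()
  if (peek_type() %in% c(NA, "keyword")) {
    if (is.na(peek())) stop("axiom truncated after subject", call. = FALSE)
    kw <- advance()
    if (kw == "SubClassOf:") return(ax_subclass(lhs, parse_expr()))
    if (kw == "EquivalentTo:") {
      exprs <- list(lhs, parse_expr())
      while (identical(peek(), ",")) { advance(); exprs[[length(exprs) + 1L]] <- parse_expr() }
      return(ax_equivalent(exprs))
    }
    if (kw == "DisjointWith:") return(ax_disjoint(list(lhs, parse_expr())))
    if (kw == "Type:") return(ax_class_assertion(parse_expr(), named_iri(lhs)))
    if (kw == "DifferentFrom:") {
      ty <- peek_type()
      other <- resolve_name(advance(), ty)
      return(ax_different(sort(c(named_iri(lhs), other))))
    }
    if (kw == "Domain:") {
      prop <- named_iri(lhs)
      if (identical(kind_of(prop), "data_property")) return(ax_data_domain(prop, parse_expr()))
      return(ax_obj_domain(prop, parse_expr()))
    }
    if (kw == "Range:") {
      prop <- named_iri(lhs)
      if (identical(kind_of(prop), "data_property")) {
        return(ax_data_range(prop, named_iri(parse_expr())))
      }
      return(ax_obj_range(prop, parse_expr()))
    }
    stop("unexpected keyword ", kw, call. = FALSE)
  }
  # fact: individual property object
  subj <- named_iri(lhs)
  prop <- named_iri(parse_primary())
  obj <- parse_literal_or_name()
  if (is_literal(obj)) return(ax_data_assertion(prop, subj, obj))
  ax_obj_assertion(prop, subj, obj)
}
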