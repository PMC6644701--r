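# Class-expression and axiom constructors: the in-memory OWL model every
# reader produces and the verbalizer/Manchester renderer consume.
#
# A class expression is a recursive list with a `kind` in
#   named | intersection | union | complement | some_values | all_values |
#   has_value | other
# `some_values`/`all_values`/`has_value` carry `property` (IRI), a `data`
# flag, and a `filler` (class expression, datatype reference, literal, or
# individual IRI). `other` carries a pre-rendered Manchester string for
# constructors outside the supported inventory; it verbalizes via the
# generic fallback path.

#' Class expression constructors
#'
#' Build the recursive class expressions that appear inside axioms:
#' named classes, intersections ("and"), unions ("or"), complements
#' ("not"), existential and universal property restrictions, and
#' has-value restrictions.
#'
#' @param iri Absolute IRI of a named class (or property for restrictions).
#' @param ... Two or more child class expressions.
#' @param property Property IRI of a restriction.
#' @param filler Filler of a restriction: a class expression, or for data
#'   restrictions a datatype reference from [ce_datatype()].
#' @param data Logical; `TRUE` for a data-property restriction.
#' @param value For [ce_has_value()], an individual IRI (string) or a
#'   literal from [owl_literal()].
#' @param manchester Pre-rendered Manchester text for an unsupported
#'   constructor.
#' @return A class expression object (class `owl_cexpr`).
#' @name class_expr
#' @examples
#' ce_some("http://example.org/hasPet", ce_named("http://example.org/Animal"))
NULL

new_cexpr <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "owl_cexpr")
}

#' @rdname class_expr
#' @export
ce_named <- function(iri) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  new_cexpr("named", iri = iri)
}

#' @rdname class_expr
#' @export
ce_and <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 2L)
  new_cexpr("intersection", children = children)
}

#' @rdname class_expr
#' @export
ce_or <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 2L)
  new_cexpr("union", children = children)
}

#' @rdname class_expr
#' @export
ce_not <- function(filler) {
  stopifnot(inherits(filler, "owl_cexpr"))
  new_cexpr("complement", children = list(filler))
}

#' @rdname class_expr
#' @export
ce_some <- function(property, filler, data = FALSE) {
  new_cexpr("some_values", property = property, filler = filler, data = data)
}

#' @rdname class_expr
#' @export
ce_only <- function(property, filler, data = FALSE) {
  new_cexpr("all_values", property = property, filler = filler, data = data)
}

#' @rdname class_expr
#' @export
ce_has_value <- function(property, value, data = FALSE) {
  new_cexpr("has_value", property = property, filler = value, data = data)
}

#' @rdname class_expr
#' @export
ce_datatype <- function(iri) {
  structure(list(kind = "datatype", iri = iri), class = "owl_datatype")
}

#' @rdname class_expr
#' @export
ce_other <- function(manchester) {
  new_cexpr("other", manchester = manchester)
}

#' Typed RDF literal
#'
#' @param value Lexical form (character scalar).
#' @param datatype Datatype IRI; defaults to `xsd:string`.
#' @return An `owl_literal` object.
#' @export
owl_literal <- function(value, datatype = xsd_iri("string")) {
  structure(list(value = as.character(value), datatype = datatype),
            class = "owl_literal")
}

is_literal <- function(x) inherits(x, "owl_literal")
is_cexpr <- function(x) inherits(x, "owl_cexpr")

# ---- axioms -----------------------------------------------------------------

new_axiom <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "owl_axiom")
}

#' Axiom constructors
#'
#' Build axioms of the 14 supported types. Class arguments are class
#' expressions (see [class_expr]); property and individual arguments are
#' IRIs; data values are [owl_literal()] objects.
#'
#' @param sub,sup Sub- and superclass expressions.
#' @param exprs A list of two or more class expressions.
#' @param expr A class expression.
#' @param individual,a,b Individual IRIs.
#' @param property Property IRI.
#' @param datatype Datatype IRI.
#' @param value An [owl_literal()].
#' @param individuals Character vector (length >= 2) of individual IRIs.
#' @return An `owl_axiom` object.
#' @name axioms
#' @examples
#' ax_subclass(ce_named("http://example.org/Dog"),
#'             ce_named("http://example.org/Animal"))
NULL

#' @rdname axioms
#' @export
ax_subclass <- function(sub, sup) {
  stopifnot(is_cexpr(sub), is_cexpr(sup))
  new_axiom("SubClassOf", sub = sub, sup = sup)
}

#' @rdname axioms
#' @export
ax_equivalent <- function(exprs) {
  stopifnot(is.list(exprs), length(exprs) >= 2L, all(vapply(exprs, is_cexpr, TRUE)))
  new_axiom("EquivalentClasses", exprs = exprs)
}

#' @rdname axioms
#' @export
ax_disjoint <- function(exprs) {
  stopifnot(is.list(exprs), length(exprs) >= 2L, all(vapply(exprs, is_cexpr, TRUE)))
  new_axiom("DisjointClasses", exprs = exprs)
}

#' @rdname axioms
#' @export
ax_class_assertion <- function(expr, individual) {
  stopifnot(is_cexpr(expr), is.character(individual))
  new_axiom("ClassAssertion", expr = expr, individual = individual)
}

#' @rdname axioms
#' @export
ax_obj_domain <- function(property, expr) {
  stopifnot(is_cexpr(expr))
  new_axiom("ObjectPropertyDomain", property = property, expr = expr)
}

#' @rdname axioms
#' @export
ax_obj_range <- function(property, expr) {
  stopifnot(is_cexpr(expr))
  new_axiom("ObjectPropertyRange", property = property, expr = expr)
}

#' @rdname axioms
#' @export
ax_data_domain <- function(property, expr) {
  stopifnot(is_cexpr(expr))
  new_axiom("DataPropertyDomain", property = property, expr = expr)
}

#' @rdname axioms
#' @export
ax_data_range <- function(property, datatype) {
  stopifnot(is.character(datatype))
  new_axiom("DataPropertyRange", property = property, datatype = datatype)
}

#' @rdname axioms
#' @export
ax_symmetric <- function(property) new_axiom("SymmetricObjectProperty", property = property)

#' @rdname axioms
#' @export
ax_functional_obj <- function(property) new_axiom("FunctionalObjectProperty", property = property)

#' @rdname axioms
#' @export
ax_functional_data <- function(property) new_axiom("FunctionalDataProperty", property = property)

#' @rdname axioms
#' @export
ax_obj_assertion <- function(property, a, b) {
  new_axiom("ObjectPropertyAssertion", property = property, a = a, b = b)
}

#' @rdname axioms
#' @export
ax_data_assertion <- function(property, a, value) {
  stopifnot(is_literal(value))
  new_axiom("DataPropertyAssertion", property = property, a = a, value = value)
}

#' @rdname axioms
#' @export
ax_different <- function(individuals) {
  stopifnot(is.character(individuals), length(individuals) >= 2L)
  new_axiom("DifferentIndividuals", individuals = individuals)
}

# ---- canonical keys (for logical-identity comparison and deduplication) -----

cexpr_key <- function(x) {
  if (inherits(x, "owl_datatype")) return(paste0("dt(", x$iri, ")"))
  if (is_literal(x)) return(paste0("lit(", x$value, "^^", x$datatype, ")"))
  if (is.character(x)) return(paste0("ind(", x, ")"))
  switch(x$kind,
    named        = paste0("<", x$iri, ">"),
    intersection = paste0("and(", paste(sort(vapply(x$children, cexpr_key, "")), collapse = ","), ")"),
    union        = paste0("or(", paste(sort(vapply(x$children, cexpr_key, "")), collapse = ","), ")"),
    complement   = paste0("not(", cexpr_key(x$children[[1]]), ")"),
    some_values  = paste0("some(", x$property, ",", cexpr_key(x$filler), ",", x$data, ")"),
    all_values   = paste0("only(", x$property, ",", cexpr_key(x$filler), ",", x$data, ")"),
    has_value    = paste0("value(", x$property, ",", cexpr_key(x$filler), ",", x$data, ")"),
    other        = paste0("other(", x$manchester, ")")
  )
}

#' Canonical identity key of an axiom
#'
#' A string that identifies an axiom up to logical identity: unordered
#' operands (equivalent/disjoint classes, different individuals) are
#' sorted, so two axioms compare equal exactly when they state the same
#' thing. Used for round-trip checks and deterministic ordering.
#'
#' @param ax An `owl_axiom`.
#' @return A character scalar.
#' @export
axiom_key <- function(ax) {
  switch(ax$type,
    SubClassOf = paste0("SubClassOf(", cexpr_key(ax$sub), ",", cexpr_key(ax$sup), ")"),
    EquivalentClasses = paste0("EquivalentClasses(",
      paste(sort(vapply(ax$exprs, cexpr_key, "")), collapse = ","), ")"),
    DisjointClasses = paste0("DisjointClasses(",
      paste(sort(vapply(ax$exprs, cexpr_key, "")), collapse = ","), ")"),
    ClassAssertion = paste0("ClassAssertion(", cexpr_key(ax$expr), ",", ax$individual, ")"),
    ObjectPropertyDomain = paste0("ObjectPropertyDomain(", ax$property, ",", cexpr_key(ax$expr), ")"),
    ObjectPropertyRange  = paste0("ObjectPropertyRange(", ax$property, ",", cexpr_key(ax$expr), ")"),
    DataPropertyDomain   = paste0("DataPropertyDomain(", ax$property, ",", cexpr_key(ax$expr), ")"),
    DataPropertyRange    = paste0("DataPropertyRange(", ax$property, ",", ax$datatype, ")"),
    SymmetricObjectProperty  = paste0("SymmetricObjectProperty(", ax$property, ")"),
    FunctionalObjectProperty = paste0("FunctionalObjectProperty(", ax$property, ")"),
    FunctionalDataProperty   = paste0("FunctionalDataProperty(", ax$property, ")"),
    ObjectPropertyAssertion  = paste0("ObjectPropertyAssertion(", ax$property, ",", ax$a, ",", ax$b, ")"),
    DataPropertyAssertion    = paste0("DataPropertyAssertion(", ax$property, ",", ax$a, ",",
                                      cexpr_key(ax$value), ")"),
    DifferentIndividuals = paste0("DifferentIndividuals(",
      paste(sort(ax$individuals), collapse = ","), ")")
  )
}

# every entity IRI referenced by an axiom, with its implied kind
axiom_refs <- function(ax) {
  refs <- list()
  add <- function(iri, kind) refs[[length(refs) + 1L]] <<- c(iri = iri, kind = kind)
  walk_expr <- function(x) {
    if (inherits(x, "owl_datatype")) { add(x$iri, "datatype"); return(invisible()) }
    if (is_literal(x) || is.null(x)) return(invisible())
    if (is.character(x)) { add(x, "named_individual"); return(invisible()) }
    switch(x$kind,
      named = add(x$iri, "class"),
      intersection = ,
      union = lapply(x$children, walk_expr),
      complement = walk_expr(x$children[[1]]),
      some_values = ,
      all_values = ,
      has_value = {
        add(x$property, if (isTRUE(x$data)) "data_property" else "object_property")
        walk_expr(x$filler)
      },
      other = NULL
    )
    invisible()
  }
  switch(ax$type,
    SubClassOf = { walk_expr(ax$sub); walk_expr(ax$sup) },
    EquivalentClasses = ,
    DisjointClasses = lapply(ax$exprs, walk_expr),
    ClassAssertion = { walk_expr(ax$expr); add(ax$individual, "named_individual") },
    ObjectPropertyDomain = ,
    ObjectPropertyRange = { add(ax$property, "object_property"); walk_expr(ax$expr) },
    DataPropertyDomain = { add(ax$property, "data_property"); walk_expr(ax$expr) },
    DataPropertyRange = { add(ax$property, "data_property"); add(ax$datatype, "datatype") },
    SymmetricObjectProperty = ,
    FunctionalObjectProperty = add(ax$property, "object_property"),
    FunctionalDataProperty = add(ax$property, "data_property"),
    ObjectPropertyAssertion = {
      add(ax$property, "object_property"); add(ax$a, "named_individual"); add(ax$b, "named_individual")
    },
    DataPropertyAssertion = { add(ax$property, "data_property"); add(ax$a, "named_individual") },
    DifferentIndividuals = lapply(ax$individuals, add, kind = "named_individual")
  )
  refs
}

#' @export
print.owl_axiom <- function(x, ...) {
  cat("<owl_axiom> ", axiom_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.owl_cexpr <- function(x, ...) {
  cat("<owl_cexpr> ", cexpr_key(x), "\n", sep = "")
  invisible(x)
}
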