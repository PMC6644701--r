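# Shared back end for the OWL/XML and functional-syntax readers. Both parse
# their input into "forms" — nested lists mirroring the functional-style
# constructor tree — which this file maps onto the axiom model.
#
# A form is one of:
#   list(op = <constructor name>, args = list(<forms>))   compound
#   list(op = <entity wrapper or "IRI">, iri = <iri>)     entity leaf
#   owl_literal(...)                                      literal leaf

form_is_leaf <- function(f) !is_literal(f) && !is.null(f$iri)
form_iri <- function(f) {
  if (!form_is_leaf(f)) stop("expected an entity in this operand position", call. = FALSE)
  f$iri
}

DECL_KINDS <- c(
  Class = "class", ObjectProperty = "object_property",
  DataProperty = "data_property", NamedIndividual = "named_individual",
  Datatype = "datatype", AnnotationProperty = "annotation_property"
)

form_cexpr <- function(f) {
  if (is_literal(f)) stop("literal in class-expression position", call. = FALSE)
  if (form_is_leaf(f)) return(ce_named(f$iri))
  a <- f$args
  switch(f$op,
    ObjectIntersectionOf = do.call(ce_and, lapply(a, form_cexpr)),
    ObjectUnionOf        = do.call(ce_or, lapply(a, form_cexpr)),
    ObjectComplementOf   = ce_not(form_cexpr(a[[1L]])),
    ObjectSomeValuesFrom = ce_some(form_iri(a[[1L]]), form_cexpr(a[[2L]])),
    ObjectAllValuesFrom  = ce_only(form_iri(a[[1L]]), form_cexpr(a[[2L]])),
    ObjectHasValue       = ce_has_value(form_iri(a[[1L]]), form_iri(a[[2L]])),
    DataSomeValuesFrom   = ce_some(form_iri(a[[1L]]), ce_datatype(form_iri(a[[2L]])), data = TRUE),
    DataAllValuesFrom    = ce_only(form_iri(a[[1L]]), ce_datatype(form_iri(a[[2L]])), data = TRUE),
    DataHasValue         = ce_has_value(form_iri(a[[1L]]), a[[2L]], data = TRUE),
    ce_other(f$op)
  )
}

form_axiom <- function(f) {
  a <- f$args
  switch(f$op,
    SubClassOf = ax_subclass(form_cexpr(a[[1L]]), form_cexpr(a[[2L]])),
    EquivalentClasses = ax_equivalent(lapply(a, form_cexpr)),
    DisjointClasses   = ax_disjoint(lapply(a, form_cexpr)),
    ClassAssertion    = ax_class_assertion(form_cexpr(a[[1L]]), form_iri(a[[2L]])),
    ObjectPropertyDomain = ax_obj_domain(form_iri(a[[1L]]), form_cexpr(a[[2L]])),
    ObjectPropertyRange  = ax_obj_range(form_iri(a[[1L]]), form_cexpr(a[[2L]])),
    DataPropertyDomain   = ax_data_domain(form_iri(a[[1L]]), form_cexpr(a[[2L]])),
    DataPropertyRange    = ax_data_range(form_iri(a[[1L]]), form_iri(a[[2L]])),
    SymmetricObjectProperty  = ax_symmetric(form_iri(a[[1L]])),
    FunctionalObjectProperty = ax_functional_obj(form_iri(a[[1L]])),
    FunctionalDataProperty   = ax_functional_data(form_iri(a[[1L]])),
    ObjectPropertyAssertion  = ax_obj_assertion(form_iri(a[[1L]]), form_iri(a[[2L]]),
                                                form_iri(a[[3L]])),
    DataPropertyAssertion    = ax_data_assertion(form_iri(a[[1L]]), form_iri(a[[2L]]), a[[3L]]),
    DifferentIndividuals = ax_different(sort(vapply(a, form_iri, ""))),
    NULL
  )
}

forms_to_model <- function(forms) {
  axioms <- list()
  labels <- character()
  declared <- list()
  unsupported <- integer()
  for (f in forms) {
    if (is_literal(f) || form_is_leaf(f)) next
    if (f$op == "Declaration") {
      ent <- f$args[[1L]]
      kind <- if (ent$op %in% names(DECL_KINDS)) DECL_KINDS[[ent$op]] else NA_character_
      # entity wrappers are leaves in OWL/XML but one-argument compounds in
      # functional syntax
      iri <- ent$iri %||% form_iri(ent$args[[1L]])
      if (!is.na(kind) && kind != "annotation_property") {
        declared[[length(declared) + 1L]] <- c(iri = iri, kind = kind)
      }
      next
    }
    if (f$op == "AnnotationAssertion") {
      prop <- form_iri(f$args[[1L]])
      if (prop == rdfs_iri("label") && is_literal(f$args[[3L]])) {
        subj <- form_iri(f$args[[2L]])
        labels <- c(labels, stats::setNames(f$args[[3L]]$value, subj))
      }
      next
    }
    if (f$op %in% c("Import", "Annotation", "Prefix")) next
    ax <- form_axiom(f)
    if (is.null(ax)) {
      unsupported[f$op] <- (if (f$op %in% names(unsupported)) unsupported[[f$op]] else 0L) + 1L
    } else {
      axioms[[length(axioms) + 1L]] <- ax
    }
  }
  declared_tb <- if (length(declared)) {
    tibble::tibble(
      iri = vapply(declared, `[[`, "", "iri"),
      kind = vapply(declared, `[[`, "", "kind")
    )
  } else tibble::tibble(iri = character(), kind = character())
  list(axioms = axioms, labels = labels, declared = declared_tb,
       unsupported = unsupported)
}
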