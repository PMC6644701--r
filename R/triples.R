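# RDF-triple intermediate layer. The Turtle and RDF/XML readers both emit a
# triple table; this file maps triples to the package's axiom model using the
# standard OWL-to-RDF mapping for the supported axiom types.
#
# Triple table columns:
#   s, p, o  : subject / predicate / object. Blank nodes are "_:<id>" strings.
#   o_kind   : "iri", "bnode" or "literal"
#   dtype    : literal datatype IRI (NA otherwise)
#   lang     : language tag (NA otherwise)

new_triples <- function(s = character(), p = character(), o = character(),
                        o_kind = character(), dtype = character(),
                        lang = character()) {
  tibble::tibble(
    s = s, p = p, o = o, o_kind = o_kind,
    dtype = as.character(dtype), lang = as.character(lang)
  )
}

is_bnode <- function(x) startsWith(x, "_:")

# predicates of axiom types outside the supported inventory, counted at load
UNSUPPORTED_PREDICATES <- c(
  "SubObjectPropertyOf" = rdfs_iri("subPropertyOf"),
  "InverseObjectProperties" = owl_iri("inverseOf"),
  "EquivalentObjectProperties" = owl_iri("equivalentProperty"),
  "DisjointObjectProperties" = owl_iri("propertyDisjointWith"),
  "SameIndividual" = owl_iri("sameAs"),
  "SubPropertyChainOf" = owl_iri("propertyChainAxiom")
)
UNSUPPORTED_TYPE_OBJECTS <- c(
  "TransitiveObjectProperty" = owl_iri("TransitiveProperty"),
  "AsymmetricObjectProperty" = owl_iri("AsymmetricProperty"),
  "ReflexiveObjectProperty" = owl_iri("ReflexiveProperty"),
  "IrreflexiveObjectProperty" = owl_iri("IrreflexiveProperty"),
  "InverseFunctionalObjectProperty" = owl_iri("InverseFunctionalProperty")
)

# Convert a triple table to (axioms, labels, declared, unsupported).
triples_to_model <- function(tr) {
  unsupported <- integer()
  bump <- function(name) {
    unsupported[name] <<- (if (name %in% names(unsupported)) unsupported[[name]] else 0L) + 1L
  }

  obj_rows <- function(s, p) tr$o[tr$s == s & tr$p == p]
  obj1 <- function(s, p) {
    v <- obj_rows(s, p)
    if (length(v)) v[[1L]] else NA_character_
  }

  # pass 1: declarations and labels
  type_rows <- tr[tr$p == rdf_iri("type") & tr$o_kind != "literal", ]
  decl_map <- c(
    "class" = owl_iri("Class"),
    "object_property" = owl_iri("ObjectProperty"),
    "data_property" = owl_iri("DatatypeProperty"),
    "named_individual" = owl_iri("NamedIndividual"),
    "datatype" = rdfs_iri("Datatype")
  )
  declared <- tibble::tibble(iri = character(), kind = character())
  for (k in names(decl_map)) {
    subj <- type_rows$s[type_rows$o == decl_map[[k]] & !is_bnode(type_rows$s)]
    if (length(subj)) {
      declared <- dplyr::bind_rows(declared, tibble::tibble(iri = unique(subj), kind = k))
    }
  }
  kind_of <- function(iri) {
    hit <- declared$kind[declared$iri == iri]
    if (length(hit)) hit[[1L]] else NA_character_
  }

  lab_rows <- tr[tr$p == rdfs_iri("label") & tr$o_kind == "literal", ]
  labels <- stats::setNames(lab_rows$o, lab_rows$s)

  # RDF collection (rdf:first / rdf:rest) starting at `node`
  rdf_list <- function(node) {
    out <- character()
    while (!is.na(node) && node != rdf_iri("nil")) {
      out <- c(out, obj1(node, rdf_iri("first")))
      node <- obj1(node, rdf_iri("rest"))
    }
    out
  }

  lit_at <- function(s, p) {
    i <- which(tr$s == s & tr$p == p & tr$o_kind == "literal")
    if (length(i)) owl_literal(tr$o[i[1L]], ifelse(is.na(tr$dtype[i[1L]]),
                                                   xsd_iri("string"), tr$dtype[i[1L]]))
    else NULL
  }

  cexpr_of <- function(node) {
    if (!is_bnode(node)) return(ce_named(node))
    prop <- obj1(node, owl_iri("onProperty"))
    if (!is.na(prop)) {
      is_data <- identical(kind_of(prop), "data_property")
      filler_of <- function(o) {
        if (!is_data) return(cexpr_of(o))
        if (!is_bnode(o)) ce_datatype(o) else ce_other(iri_fragment(o))
      }
      sv <- obj1(node, owl_iri("someValuesFrom"))
      if (!is.na(sv)) return(ce_some(prop, filler_of(sv), data = is_data))
      av <- obj1(node, owl_iri("allValuesFrom"))
      if (!is.na(av)) return(ce_only(prop, filler_of(av), data = is_data))
      hv_i <- which(tr$s == node & tr$p == owl_iri("hasValue"))
      if (length(hv_i)) {
        i <- hv_i[1L]
        val <- if (tr$o_kind[i] == "literal") {
          owl_literal(tr$o[i], ifelse(is.na(tr$dtype[i]), xsd_iri("string"), tr$dtype[i]))
        } else tr$o[i]
        return(ce_has_value(prop, val, data = is_data))
      }
      # cardinality and other restriction flavours: generic fallback node
      card_p <- c("minCardinality", "maxCardinality", "cardinality",
                  "minQualifiedCardinality", "maxQualifiedCardinality",
                  "qualifiedCardinality")
      for (cp in card_p) {
        lit <- lit_at(node, owl_iri(cp))
        if (!is.null(lit)) {
          kw <- c(minCardinality = "min", maxCardinality = "max", cardinality = "exactly",
                  minQualifiedCardinality = "min", maxQualifiedCardinality = "max",
                  qualifiedCardinality = "exactly")[[cp]]
          return(ce_other(paste(iri_fragment(prop), kw, lit$value)))
        }
      }
      self <- lit_at(node, owl_iri("hasSelf"))
      if (!is.null(self)) return(ce_other(paste(iri_fragment(prop), "Self")))
      return(ce_other(paste(iri_fragment(prop), "some owl:Thing")))
    }
    ix <- obj1(node, owl_iri("intersectionOf"))
    if (!is.na(ix)) return(do.call(ce_and, lapply(rdf_list(ix), cexpr_of)))
    un <- obj1(node, owl_iri("unionOf"))
    if (!is.na(un)) return(do.call(ce_or, lapply(rdf_list(un), cexpr_of)))
    cm <- obj1(node, owl_iri("complementOf"))
    if (!is.na(cm)) return(ce_not(cexpr_of(cm)))
    oo <- obj1(node, owl_iri("oneOf"))
    if (!is.na(oo)) return(ce_other(paste0("{", paste(vapply(rdf_list(oo), iri_fragment, ""),
                                                      collapse = ", "), "}")))
    ce_other(iri_fragment(node))
  }

  owl_vocab_ns <- c(RDF_NS, RDFS_NS, OWL_NS)
  in_vocab <- function(iri) any(startsWith(iri, owl_vocab_ns))

  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  for (i in seq_len(nrow(tr))) {
    s <- tr$s[i]; p <- tr$p[i]; o <- tr$o[i]; ok <- tr$o_kind[i]
    if (p == rdf_iri("type")) {
      if (ok == "literal" || is_bnode(s)) next
      if (o == owl_iri("SymmetricProperty")) { add(ax_symmetric(s)); next }
      if (o == owl_iri("FunctionalProperty")) {
        if (identical(kind_of(s), "data_property")) add(ax_functional_data(s))
        else add(ax_functional_obj(s))
        next
      }
      if (o %in% UNSUPPORTED_TYPE_OBJECTS) {
        bump(names(UNSUPPORTED_TYPE_OBJECTS)[UNSUPPORTED_TYPE_OBJECTS == o]); next
      }
      if (ok == "bnode" || !in_vocab(o)) {
        # a type triple pointing at a real class: ClassAssertion
        add(ax_class_assertion(cexpr_of(o), s))
      }
      next
    }
    if (p == rdfs_iri("subClassOf")) { add(ax_subclass(cexpr_of(s), cexpr_of(o))); next }
    if (p == owl_iri("equivalentClass")) {
      add(ax_equivalent(list(cexpr_of(s), cexpr_of(o)))); next
    }
    if (p == owl_iri("disjointWith")) {
      add(ax_disjoint(list(cexpr_of(s), cexpr_of(o)))); next
    }
    if (p == rdfs_iri("domain")) {
      if (identical(kind_of(s), "data_property")) add(ax_data_domain(s, cexpr_of(o)))
      else add(ax_obj_domain(s, cexpr_of(o)))
      next
    }
    if (p == rdfs_iri("range")) {
      if (identical(kind_of(s), "data_property") || startsWith(o, XSD_NS)) {
        add(ax_data_range(s, o))
      } else {
        add(ax_obj_range(s, cexpr_of(o)))
      }
      next
    }
    if (p == owl_iri("differentFrom")) { add(ax_different(sort(c(s, o)))); next }
    if (p %in% c(owl_iri("distinctMembers"), owl_iri("members"))) {
      members <- rdf_list(o)
      if (length(members) >= 2L) add(ax_different(sort(members)))
      next
    }
    if (p %in% UNSUPPORTED_PREDICATES) {
      bump(names(UNSUPPORTED_PREDICATES)[UNSUPPORTED_PREDICATES == p]); next
    }
    pk <- kind_of(p)
    if (identical(pk, "object_property") && ok != "literal" && !is_bnode(s)) {
      add(ax_obj_assertion(p, s, o)); next
    }
    if (identical(pk, "data_property") && ok == "literal" && !is_bnode(s)) {
      add(ax_data_assertion(p, s, owl_literal(
        o, ifelse(is.na(tr$dtype[i]), xsd_iri("string"), tr$dtype[i]))))
      next
    }
    # annotations other than rdfs:label, list plumbing, ontology header: ignored
  }

  list(axioms = axioms, labels = labels, declared = declared,
       unsupported = unsupported)
}
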