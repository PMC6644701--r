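# Offline fixture generation: small ontologies in the style of a
# family-domain teaching ontology, written deterministically in all four
# supported serializations, plus seed-reproducible synthetic expert ratings.
#
# A fixture model is a list:
#   prefixes     named character (prefix -> namespace IRI)
#   ontology_iri character
#   declarations tibble(iri, kind)
#   labels       named character (IRI -> rdfs:label; omissions deliberate)
#   axioms       list of owl_axiom

fx_name <- function(iri, prefixes) {
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (startsWith(iri, ns)) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local)) return(paste0(pfx, ":", local))
    }
  }
  paste0("<", iri, ">")
}

# ---- fixture models ---------------------------------------------------------

paper_examples_model <- function() {
  obo <- function(x) paste0(OBO_NS, x)
  prefixes <- c(ICO = paste0(OBO_NS, "ICO_"),
                IAO = paste0(OBO_NS, "IAO_"),
                TEO = paste0(OBO_NS, "TEO_"))
  classes <- c("ICO_0000062", "ICO_0000073", "ICO_0000171", "ICO_0000064",
               "TEO_0000048", "TEO_0000084", "TEO_0000006")
  declarations <- dplyr::bind_rows(
    tibble::tibble(iri = obo(classes), kind = "class"),
    tibble::tibble(iri = obo("IAO_0000136"), kind = "object_property")
  )
  labels <- c(
    "human subject unable to give informed consent",
    "human subject",
    "answer option text entity",
    "study requiring informed consent",
    "Saturday",
    "week day",
    "duration measurement",
    "is about"
  )
  names(labels) <- obo(c(classes, "IAO_0000136"))
  # IAO_0000032 is deliberately neither declared nor labeled: it plays the
  # unresolved external term whose sentence falls back to "iao 0000032"
  axioms <- list(
    ax_subclass(ce_named(obo("ICO_0000062")), ce_named(obo("ICO_0000073"))),
    ax_subclass(ce_named(obo("ICO_0000171")),
                ce_some(obo("IAO_0000136"), ce_named(obo("ICO_0000064")))),
    ax_subclass(ce_named(obo("TEO_0000048")), ce_named(obo("TEO_0000084"))),
    ax_subclass(ce_named(obo("TEO_0000006")), ce_named(obo("IAO_0000032")))
  )
  list(prefixes = prefixes, ontology_iri = "http://example.org/fixtures/worked-examples",
       declarations = declarations, labels = labels, axioms = axioms)
}

people_model <- function() {
  ns <- "http://example.org/people#"
  p <- function(x) paste0(ns, x)
  classes <- c(Person = "person", Man = "man", Woman = "woman", Adult = "adult",
               Child = "child", Parent = "parent", Grandparent = "grandparent",
               PetOwner = "pet owner", Animal = "animal", Pet = "pet",
               Dog = "dog", Cat = "cat", Driver = "driver")
  obj_props <- c(hasChild = "has child", hasPet = "has pet", hasSpouse = "has spouse",
                 knows = "knows", likes = "likes", isParentOf = "is parent of")
  data_props <- c(hasAge = "has age", hasName = "has name")
  individuals <- c(Alice = "Alice", Bob = "Bob", Carol = "Carol", David = "David",
                   Eve = "Eve", Frank = "Frank", Grace = "Grace", Rex = "Rex",
                   Tom = "Tom")
  declarations <- dplyr::bind_rows(
    tibble::tibble(iri = p(names(classes)), kind = "class"),
    tibble::tibble(iri = p(names(obj_props)), kind = "object_property"),
    tibble::tibble(iri = p(names(data_props)), kind = "data_property"),
    tibble::tibble(iri = p(names(individuals)), kind = "named_individual")
  )
  labels <- c(classes, obj_props, data_props, individuals)
  names(labels) <- p(names(labels))
  sub <- function(a, b) ax_subclass(ce_named(p(a)), ce_named(p(b)))
  axioms <- list(
    # 11 subclass axioms
    sub("Man", "Person"), sub("Woman", "Person"), sub("Parent", "Person"),
    sub("Grandparent", "Parent"), sub("Child", "Person"), sub("Adult", "Person"),
    sub("Driver", "Adult"), sub("Dog", "Animal"), sub("Cat", "Animal"),
    sub("Pet", "Animal"), sub("PetOwner", "Person"),
    ax_equivalent(list(ce_named(p("PetOwner")),
                       ce_some(p("hasPet"), ce_named(p("Animal"))))),
    ax_disjoint(list(ce_named(p("Man")), ce_named(p("Woman")))),
    ax_disjoint(list(ce_named(p("Dog")), ce_named(p("Cat")))),
    ax_class_assertion(ce_named(p("Woman")), p("Alice")),
    ax_class_assertion(ce_named(p("Man")), p("Bob")),
    ax_class_assertion(ce_named(p("Dog")), p("Rex")),
    ax_class_assertion(ce_named(p("Cat")), p("Tom")),
    ax_class_assertion(ce_named(p("Child")), p("Carol")),
    # 4 object-property domains
    ax_obj_domain(p("hasChild"), ce_named(p("Person"))),
    ax_obj_domain(p("hasPet"), ce_named(p("Person"))),
    ax_obj_domain(p("knows"), ce_named(p("Person"))),
    ax_obj_domain(p("likes"), ce_named(p("Person"))),
    ax_obj_range(p("hasChild"), ce_named(p("Person"))),
    ax_obj_range(p("hasPet"), ce_named(p("Pet"))),
    ax_data_domain(p("hasAge"), ce_named(p("Person"))),
    ax_data_range(p("hasAge"), xsd_iri("integer")),
    ax_data_range(p("hasName"), xsd_iri("string")),
    ax_symmetric(p("hasSpouse")),
    ax_functional_obj(p("hasSpouse")),
    ax_functional_data(p("hasAge")),
    ax_obj_assertion(p("hasChild"), p("Alice"), p("Carol")),
    ax_obj_assertion(p("knows"), p("Bob"), p("Alice")),
    ax_obj_assertion(p("isParentOf"), p("Alice"), p("Carol")),
    ax_obj_assertion(p("hasSpouse"), p("Bob"), p("Alice")),
    ax_obj_assertion(p("likes"), p("David"), p("Eve")),
    ax_obj_assertion(p("knows"), p("Frank"), p("Grace")),
    ax_data_assertion(p("hasAge"), p("Alice"), owl_literal("34", xsd_iri("integer"))),
    ax_data_assertion(p("hasName"), p("Rex"), owl_literal("Rex")),
    ax_different(c(p("Alice"), p("Bob")))
  )
  list(prefixes = c(peo = ns), ontology_iri = "http://example.org/people",
       declarations = declarations, labels = labels, axioms = axioms)
}

# ---- serializers ------------------------------------------------------------

KIND_CLASS_IRI <- c(
  class = "Class", object_property = "ObjectProperty",
  data_property = "DatatypeProperty", named_individual = "NamedIndividual"
)

ttl_expr <- function(expr, prefixes) {
  nm <- function(iri) fx_name(iri, c(prefixes, BASE_PREFIXES))
  if (inherits(expr, "owl_datatype")) return(nm(expr$iri))
  switch(expr$kind,
    named = nm(expr$iri),
    some_values = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", nm(expr$property),
                         " ; owl:someValuesFrom ", ttl_expr(expr$filler, prefixes), " ]"),
    all_values = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", nm(expr$property),
                        " ; owl:allValuesFrom ", ttl_expr(expr$filler, prefixes), " ]"),
    has_value = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", nm(expr$property),
                       " ; owl:hasValue ", ttl_term(expr$filler, prefixes), " ]"),
    intersection = paste0("[ rdf:type owl:Class ; owl:intersectionOf ( ",
                          paste(vapply(expr$children, ttl_expr, "", prefixes), collapse = " "),
                          " ) ]"),
    union = paste0("[ rdf:type owl:Class ; owl:unionOf ( ",
                   paste(vapply(expr$children, ttl_expr, "", prefixes), collapse = " "),
                   " ) ]"),
    complement = paste0("[ rdf:type owl:Class ; owl:complementOf ",
                        ttl_expr(expr$children[[1L]], prefixes), " ]")
  )
}

ttl_literal <- function(lit) {
  if (lit$datatype == xsd_iri("string")) {
    paste0("\"", gsub("\"", "\\\\\"", lit$value), "\"")
  } else if (lit$datatype %in% c(xsd_iri("integer"), xsd_iri("decimal"),
                                 xsd_iri("boolean"))) {
    lit$value
  } else {
    paste0("\"", lit$value, "\"^^", fx_name(lit$datatype, BASE_PREFIXES))
  }
}

ttl_term <- function(x, prefixes) {
  if (is_literal(x)) ttl_literal(x)
  else if (is.character(x)) fx_name(x, c(prefixes, BASE_PREFIXES))
  else ttl_expr(x, prefixes)
}

write_fixture_turtle <- function(model, path) {
  prefixes <- model$prefixes
  nm <- function(iri) fx_name(iri, c(prefixes, BASE_PREFIXES))
  lines <- c(
    vapply(names(BASE_PREFIXES), function(pfx) {
      paste0("@prefix ", pfx, ": <", BASE_PREFIXES[[pfx]], "> .")
    }, ""),
    vapply(names(prefixes), function(pfx) {
      paste0("@prefix ", pfx, ": <", prefixes[[pfx]], "> .")
    }, ""),
    "",
    paste0("<", model$ontology_iri, "> a owl:Ontology ."),
    ""
  )
  decl <- model$declarations
  for (i in seq_len(nrow(decl))) {
    lines <- c(lines, paste0(nm(decl$iri[i]), " a owl:", KIND_CLASS_IRI[[decl$kind[i]]], " ."))
    lab <- model$labels[decl$iri[i]]
    if (!is.na(lab)) {
      lines <- c(lines, paste0(nm(decl$iri[i]), " rdfs:label \"", lab, "\" ."))
    }
  }
  lines <- c(lines, "")
  for (ax in model$axioms) {
    stmt <- switch(ax$type,
      SubClassOf = paste(ttl_expr(ax$sub, prefixes), "rdfs:subClassOf",
                         ttl_expr(ax$sup, prefixes)),
      EquivalentClasses = paste(ttl_expr(ax$exprs[[1L]], prefixes), "owl:equivalentClass",
                                ttl_expr(ax$exprs[[2L]], prefixes)),
      DisjointClasses = paste(ttl_expr(ax$exprs[[1L]], prefixes), "owl:disjointWith",
                              ttl_expr(ax$exprs[[2L]], prefixes)),
      ClassAssertion = paste(nm(ax$individual), "a", ttl_expr(ax$expr, prefixes)),
      ObjectPropertyDomain = paste(nm(ax$property), "rdfs:domain", ttl_expr(ax$expr, prefixes)),
      ObjectPropertyRange = paste(nm(ax$property), "rdfs:range", ttl_expr(ax$expr, prefixes)),
      DataPropertyDomain = paste(nm(ax$property), "rdfs:domain", ttl_expr(ax$expr, prefixes)),
      DataPropertyRange = paste(nm(ax$property), "rdfs:range", nm(ax$datatype)),
      SymmetricObjectProperty = paste(nm(ax$property), "a owl:SymmetricProperty"),
      FunctionalObjectProperty = paste(nm(ax$property), "a owl:FunctionalProperty"),
      FunctionalDataProperty = paste(nm(ax$property), "a owl:FunctionalProperty"),
      ObjectPropertyAssertion = paste(nm(ax$a), nm(ax$property), nm(ax$b)),
      DataPropertyAssertion = paste(nm(ax$a), nm(ax$property), ttl_literal(ax$value)),
      DifferentIndividuals = {
        if (length(ax$individuals) == 2L) {
          paste(nm(ax$individuals[[1L]]), "owl:differentFrom", nm(ax$individuals[[2L]]))
        } else {
          paste0("[ rdf:type owl:AllDifferent ; owl:distinctMembers ( ",
                 paste(vapply(ax$individuals, nm, ""), collapse = " "), " ) ]")
        }
      }
    )
    lines <- c(lines, paste0(stmt, " ."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

rx_expr <- function(expr, prefixes, indent) {
  pad <- strrep(" ", indent)
  if (expr$kind == "named") {
    return(paste0(pad, "<rdf:Description rdf:about=\"", expr$iri, "\"/>"))
  }
  sub_el <- function(tag, filler) {
    if (is.character(filler)) {
      paste0(pad, "  <owl:", tag, " rdf:resource=\"", filler, "\"/>")
    } else if (is_literal(filler)) {
      paste0(pad, "  <owl:", tag, " rdf:datatype=\"", filler$datatype, "\">",
             xml_escape(filler$value), "</owl:", tag, ">")
    } else if (inherits(filler, "owl_datatype")) {
      paste0(pad, "  <owl:", tag, " rdf:resource=\"", filler$iri, "\"/>")
    } else if (filler$kind == "named") {
      paste0(pad, "  <owl:", tag, " rdf:resource=\"", filler$iri, "\"/>")
    } else {
      c(paste0(pad, "  <owl:", tag, ">"),
        rx_expr(filler, prefixes, indent + 4L),
        paste0(pad, "  </owl:", tag, ">"))
    }
  }
  switch(expr$kind,
    some_values = c(
      paste0(pad, "<owl:Restriction>"),
      paste0(pad, "  <owl:onProperty rdf:resource=\"", expr$property, "\"/>"),
      sub_el("someValuesFrom", expr$filler),
      paste0(pad, "</owl:Restriction>")
    ),
    all_values = c(
      paste0(pad, "<owl:Restriction>"),
      paste0(pad, "  <owl:onProperty rdf:resource=\"", expr$property, "\"/>"),
      sub_el("allValuesFrom", expr$filler),
      paste0(pad, "</owl:Restriction>")
    ),
    has_value = c(
      paste0(pad, "<owl:Restriction>"),
      paste0(pad, "  <owl:onProperty rdf:resource=\"", expr$property, "\"/>"),
      sub_el("hasValue", expr$filler),
      paste0(pad, "</owl:Restriction>")
    ),
    intersection = c(
      paste0(pad, "<owl:Class>"),
      paste0(pad, "  <owl:intersectionOf rdf:parseType=\"Collection\">"),
      unlist(lapply(expr$children, rx_expr, prefixes = prefixes, indent = indent + 4L)),
      paste0(pad, "  </owl:intersectionOf>"),
      paste0(pad, "</owl:Class>")
    ),
    union = c(
      paste0(pad, "<owl:Class>"),
      paste0(pad, "  <owl:unionOf rdf:parseType=\"Collection\">"),
      unlist(lapply(expr$children, rx_expr, prefixes = prefixes, indent = indent + 4L)),
      paste0(pad, "  </owl:unionOf>"),
      paste0(pad, "</owl:Class>")
    ),
    complement = c(
      paste0(pad, "<owl:Class>"),
      if (expr$children[[1L]]$kind == "named") {
        paste0(pad, "  <owl:complementOf rdf:resource=\"", expr$children[[1L]]$iri, "\"/>")
      } else {
        c(paste0(pad, "  <owl:complementOf>"),
          rx_expr(expr$children[[1L]], prefixes, indent + 4L),
          paste0(pad, "  </owl:complementOf>"))
      },
      paste0(pad, "</owl:Class>")
    )
  )
}

# property element: nested expression or rdf:resource shorthand
rx_prop <- function(tag, expr, prefixes) {
  if (expr$kind == "named") {
    paste0("    <", tag, " rdf:resource=\"", expr$iri, "\"/>")
  } else {
    c(paste0("    <", tag, ">"),
      rx_expr(expr, prefixes, 6L),
      paste0("    </", tag, ">"))
  }
}

write_fixture_rdfxml <- function(model, path) {
  prefixes <- model$prefixes
  qname <- function(iri) {
    cu <- fx_name(iri, prefixes)
    if (startsWith(cu, "<")) stop("cannot QName-ify predicate ", iri, call. = FALSE)
    sub(":", ":", cu, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF",
    paste0("    xmlns:", names(BASE_PREFIXES), "=\"", unname(BASE_PREFIXES), "\""),
    paste0("    xmlns:", names(prefixes), "=\"", unname(prefixes), "\""),
    "    >",
    paste0("  <owl:Ontology rdf:about=\"", model$ontology_iri, "\"/>")
  )
  decl <- model$declarations
  for (i in seq_len(nrow(decl))) {
    iri <- decl$iri[i]
    tag <- paste0("owl:", KIND_CLASS_IRI[[decl$kind[i]]])
    lab <- model$labels[iri]
    if (is.na(lab)) {
      lines <- c(lines, paste0("  <", tag, " rdf:about=\"", iri, "\"/>"))
    } else {
      lines <- c(lines,
                 paste0("  <", tag, " rdf:about=\"", iri, "\">"),
                 paste0("    <rdfs:label>", xml_escape(lab), "</rdfs:label>"),
                 paste0("  </", tag, ">"))
    }
  }
  about <- function(iri, body) {
    c(paste0("  <rdf:Description rdf:about=\"", iri, "\">"), body,
      "  </rdf:Description>")
  }
  for (ax in model$axioms) {
    block <- switch(ax$type,
      SubClassOf = about(ax$sub$iri, rx_prop("rdfs:subClassOf", ax$sup, prefixes)),
      EquivalentClasses = about(ax$exprs[[1L]]$iri,
                                rx_prop("owl:equivalentClass", ax$exprs[[2L]], prefixes)),
      DisjointClasses = about(ax$exprs[[1L]]$iri,
                              rx_prop("owl:disjointWith", ax$exprs[[2L]], prefixes)),
      ClassAssertion = about(ax$individual, rx_prop("rdf:type", ax$expr, prefixes)),
      ObjectPropertyDomain = about(ax$property, rx_prop("rdfs:domain", ax$expr, prefixes)),
      ObjectPropertyRange = about(ax$property, rx_prop("rdfs:range", ax$expr, prefixes)),
      DataPropertyDomain = about(ax$property, rx_prop("rdfs:domain", ax$expr, prefixes)),
      DataPropertyRange = about(ax$property,
                                paste0("    <rdfs:range rdf:resource=\"", ax$datatype, "\"/>")),
      SymmetricObjectProperty = about(ax$property,
        paste0("    <rdf:type rdf:resource=\"", owl_iri("SymmetricProperty"), "\"/>")),
      FunctionalObjectProperty = about(ax$property,
        paste0("    <rdf:type rdf:resource=\"", owl_iri("FunctionalProperty"), "\"/>")),
      FunctionalDataProperty = about(ax$property,
        paste0("    <rdf:type rdf:resource=\"", owl_iri("FunctionalProperty"), "\"/>")),
      ObjectPropertyAssertion = about(ax$a,
        paste0("    <", qname(ax$property), " rdf:resource=\"", ax$b, "\"/>")),
      DataPropertyAssertion = about(ax$a,
        paste0("    <", qname(ax$property), " rdf:datatype=\"", ax$value$datatype, "\">",
               xml_escape(ax$value$value), "</", qname(ax$property), ">")),
      DifferentIndividuals = {
        if (length(ax$individuals) == 2L) {
          about(ax$individuals[[1L]],
                paste0("    <owl:differentFrom rdf:resource=\"", ax$individuals[[2L]], "\"/>"))
        } else {
          c("  <owl:AllDifferent>",
            "    <owl:distinctMembers rdf:parseType=\"Collection\">",
            paste0("      <rdf:Description rdf:about=\"", ax$individuals, "\"/>"),
            "    </owl:distinctMembers>",
            "  </owl:AllDifferent>")
        }
      }
    )
    lines <- c(lines, block)
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

ox_expr <- function(x) {
  if (inherits(x, "owl_datatype")) return(paste0("<Datatype IRI=\"", x$iri, "\"/>"))
  if (is_literal(x)) {
    return(paste0("<Literal datatypeIRI=\"", x$datatype, "\">",
                  xml_escape(x$value), "</Literal>"))
  }
  if (is.character(x)) return(paste0("<NamedIndividual IRI=\"", x, "\"/>"))
  switch(x$kind,
    named = paste0("<Class IRI=\"", x$iri, "\"/>"),
    some_values = c(
      if (isTRUE(x$data)) "<DataSomeValuesFrom>" else "<ObjectSomeValuesFrom>",
      paste0("  <", if (isTRUE(x$data)) "DataProperty" else "ObjectProperty",
             " IRI=\"", x$property, "\"/>"),
      paste0("  ", ox_expr(x$filler)),
      if (isTRUE(x$data)) "</DataSomeValuesFrom>" else "</ObjectSomeValuesFrom>"
    ),
    all_values = c(
      if (isTRUE(x$data)) "<DataAllValuesFrom>" else "<ObjectAllValuesFrom>",
      paste0("  <", if (isTRUE(x$data)) "DataProperty" else "ObjectProperty",
             " IRI=\"", x$property, "\"/>"),
      paste0("  ", ox_expr(x$filler)),
      if (isTRUE(x$data)) "</DataAllValuesFrom>" else "</ObjectAllValuesFrom>"
    ),
    has_value = c(
      if (isTRUE(x$data)) "<DataHasValue>" else "<ObjectHasValue>",
      paste0("  <", if (isTRUE(x$data)) "DataProperty" else "ObjectProperty",
             " IRI=\"", x$property, "\"/>"),
      paste0("  ", ox_expr(x$filler)),
      if (isTRUE(x$data)) "</DataHasValue>" else "</ObjectHasValue>"
    ),
    intersection = c("<ObjectIntersectionOf>",
                     paste0("  ", unlist(lapply(x$children, ox_expr))),
                     "</ObjectIntersectionOf>"),
    union = c("<ObjectUnionOf>",
              paste0("  ", unlist(lapply(x$children, ox_expr))),
              "</ObjectUnionOf>"),
    complement = c("<ObjectComplementOf>",
                   paste0("  ", unlist(lapply(x$children, ox_expr))),
                   "</ObjectComplementOf>")
  )
}

write_fixture_owlxml <- function(model, path) {
  decl <- model$declarations
  kind_el <- c(class = "Class", object_property = "ObjectProperty",
               data_property = "DataProperty", named_individual = "NamedIndividual")
  el <- function(tag, ...) c(paste0("  <", tag, ">"), paste0("    ", c(...)),
                             paste0("  </", tag, ">"))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<Ontology xmlns=\"http://www.w3.org/2002/07/owl#\" ontologyIRI=\"",
           model$ontology_iri, "\">"),
    vapply(names(BASE_PREFIXES), function(pfx) {
      paste0("  <Prefix name=\"", pfx, "\" IRI=\"", BASE_PREFIXES[[pfx]], "\"/>")
    }, ""),
    vapply(names(model$prefixes), function(pfx) {
      paste0("  <Prefix name=\"", pfx, "\" IRI=\"", model$prefixes[[pfx]], "\"/>")
    }, "")
  )
  for (i in seq_len(nrow(decl))) {
    lines <- c(lines, el("Declaration",
                         paste0("<", kind_el[[decl$kind[i]]], " IRI=\"", decl$iri[i], "\"/>")))
  }
  for (iri in names(model$labels)) {
    lab <- model$labels[[iri]]
    lines <- c(lines, el("AnnotationAssertion",
      "<AnnotationProperty abbreviatedIRI=\"rdfs:label\"/>",
      paste0("<IRI>", iri, "</IRI>"),
      paste0("<Literal>", xml_escape(lab), "</Literal>")))
  }
  cls <- function(e) ox_expr(e)
  prop <- function(iri, data = FALSE) {
    paste0("<", if (data) "DataProperty" else "ObjectProperty", " IRI=\"", iri, "\"/>")
  }
  ind <- function(iri) paste0("<NamedIndividual IRI=\"", iri, "\"/>")
  for (ax in model$axioms) {
    body <- switch(ax$type,
      SubClassOf = c(cls(ax$sub), cls(ax$sup)),
      EquivalentClasses = unlist(lapply(ax$exprs, cls)),
      DisjointClasses = unlist(lapply(ax$exprs, cls)),
      ClassAssertion = c(cls(ax$expr), ind(ax$individual)),
      ObjectPropertyDomain = c(prop(ax$property), cls(ax$expr)),
      ObjectPropertyRange = c(prop(ax$property), cls(ax$expr)),
      DataPropertyDomain = c(prop(ax$property, TRUE), cls(ax$expr)),
      DataPropertyRange = c(prop(ax$property, TRUE),
                            paste0("<Datatype IRI=\"", ax$datatype, "\"/>")),
      SymmetricObjectProperty = prop(ax$property),
      FunctionalObjectProperty = prop(ax$property),
      FunctionalDataProperty = prop(ax$property, TRUE),
      ObjectPropertyAssertion = c(prop(ax$property), ind(ax$a), ind(ax$b)),
      DataPropertyAssertion = c(prop(ax$property, TRUE), ind(ax$a),
                                paste0("<Literal datatypeIRI=\"", ax$value$datatype, "\">",
                                       xml_escape(ax$value$value), "</Literal>")),
      DifferentIndividuals = vapply(ax$individuals, ind, "")
    )
    lines <- c(lines, el(ax$type, body))
  }
  lines <- c(lines, "</Ontology>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

fn_expr <- function(x, prefixes) {
  nm <- function(iri) fx_name(iri, c(prefixes, BASE_PREFIXES))
  if (inherits(x, "owl_datatype")) return(nm(x$iri))
  if (is_literal(x)) return(fn_literal(x, prefixes))
  if (is.character(x)) return(nm(x))
  switch(x$kind,
    named = nm(x$iri),
    some_values = paste0(if (isTRUE(x$data)) "DataSomeValuesFrom(" else "ObjectSomeValuesFrom(",
                         nm(x$property), " ", fn_expr(x$filler, prefixes), ")"),
    all_values = paste0(if (isTRUE(x$data)) "DataAllValuesFrom(" else "ObjectAllValuesFrom(",
                        nm(x$property), " ", fn_expr(x$filler, prefixes), ")"),
    has_value = paste0(if (isTRUE(x$data)) "DataHasValue(" else "ObjectHasValue(",
                       nm(x$property), " ", fn_expr(x$filler, prefixes), ")"),
    intersection = paste0("ObjectIntersectionOf(",
                          paste(vapply(x$children, fn_expr, "", prefixes), collapse = " "), ")"),
    union = paste0("ObjectUnionOf(",
                   paste(vapply(x$children, fn_expr, "", prefixes), collapse = " "), ")"),
    complement = paste0("ObjectComplementOf(", fn_expr(x$children[[1L]], prefixes), ")")
  )
}

fn_literal <- function(lit, prefixes) {
  if (lit$datatype == xsd_iri("string")) {
    paste0("\"", gsub("\"", "\\\\\"", lit$value), "\"")
  } else {
    paste0("\"", lit$value, "\"^^", fx_name(lit$datatype, BASE_PREFIXES))
  }
}

write_fixture_functional <- function(model, path) {
  prefixes <- model$prefixes
  nm <- function(iri) fx_name(iri, c(prefixes, BASE_PREFIXES))
  kind_fn <- c(class = "Class", object_property = "ObjectProperty",
               data_property = "DataProperty", named_individual = "NamedIndividual")
  lines <- c(
    vapply(names(BASE_PREFIXES), function(pfx) {
      paste0("Prefix(", pfx, ":=<", BASE_PREFIXES[[pfx]], ">)")
    }, ""),
    vapply(names(prefixes), function(pfx) {
      paste0("Prefix(", pfx, ":=<", prefixes[[pfx]], ">)")
    }, ""),
    paste0("Ontology(<", model$ontology_iri, ">")
  )
  decl <- model$declarations
  for (i in seq_len(nrow(decl))) {
    lines <- c(lines, paste0("Declaration(", kind_fn[[decl$kind[i]]], "(",
                             nm(decl$iri[i]), "))"))
  }
  for (iri in names(model$labels)) {
    lines <- c(lines, paste0("AnnotationAssertion(rdfs:label ", nm(iri), " \"",
                             gsub("\"", "\\\\\"", model$labels[[iri]]), "\")"))
  }
  ex <- function(e) fn_expr(e, prefixes)
  for (ax in model$axioms) {
    stmt <- switch(ax$type,
      SubClassOf = paste0("SubClassOf(", ex(ax$sub), " ", ex(ax$sup), ")"),
      EquivalentClasses = paste0("EquivalentClasses(",
                                 paste(vapply(ax$exprs, ex, ""), collapse = " "), ")"),
      DisjointClasses = paste0("DisjointClasses(",
                               paste(vapply(ax$exprs, ex, ""), collapse = " "), ")"),
      ClassAssertion = paste0("ClassAssertion(", ex(ax$expr), " ", nm(ax$individual), ")"),
      ObjectPropertyDomain = paste0("ObjectPropertyDomain(", nm(ax$property), " ",
                                    ex(ax$expr), ")"),
      ObjectPropertyRange = paste0("ObjectPropertyRange(", nm(ax$property), " ",
                                   ex(ax$expr), ")"),
      DataPropertyDomain = paste0("DataPropertyDomain(", nm(ax$property), " ",
                                  ex(ax$expr), ")"),
      DataPropertyRange = paste0("DataPropertyRange(", nm(ax$property), " ",
                                 nm(ax$datatype), ")"),
      SymmetricObjectProperty = paste0("SymmetricObjectProperty(", nm(ax$property), ")"),
      FunctionalObjectProperty = paste0("FunctionalObjectProperty(", nm(ax$property), ")"),
      FunctionalDataProperty = paste0("FunctionalDataProperty(", nm(ax$property), ")"),
      ObjectPropertyAssertion = paste0("ObjectPropertyAssertion(", nm(ax$property), " ",
                                       nm(ax$a), " ", nm(ax$b), ")"),
      DataPropertyAssertion = paste0("DataPropertyAssertion(", nm(ax$property), " ",
                                     nm(ax$a), " ", fn_literal(ax$value, prefixes), ")"),
      DifferentIndividuals = paste0("DifferentIndividuals(",
                                    paste(vapply(ax$individuals, nm, ""), collapse = " "), ")")
    )
    lines <- c(lines, stmt)
  }
  lines <- c(lines, ")")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

FIXTURE_WRITERS <- list(
  turtle = write_fixture_turtle,
  rdfxml = write_fixture_rdfxml,
  owlxml = write_fixture_owlxml,
  functional = write_fixture_functional
)

FIXTURE_EXT <- c(turtle = "ttl", rdfxml = "owl", owlxml = "owx", functional = "ofn")

write_fixture <- function(model, dir, stem, formats) {
  paths <- character()
  for (fmt in formats) {
    path <- file.path(dir, paste0(stem, ".", FIXTURE_EXT[[fmt]]))
    FIXTURE_WRITERS[[fmt]](model, path)
    paths[[fmt]] <- path
  }
  paths
}

#' Write the worked-example ontology
#'
#' A four-axiom ontology containing the SubClassOf axioms behind the
#' package's reference sentences, including one deliberately unlabeled
#' external term (`IAO_0000032`) exercising the IRI-fragment fallback.
#'
#' @param dir Output directory.
#' @param formats Any of `"turtle"`, `"rdfxml"`, `"owlxml"`, `"functional"`.
#' @return Named character vector of written paths (invisibly named by
#'   format).
#' @export
#' @examples
#' write_paper_examples(tempdir(), formats = "turtle")
write_paper_examples <- function(dir, formats = c("turtle", "rdfxml")) {
  formats <- match.arg(formats, names(FIXTURE_WRITERS), several.ok = TRUE)
  write_fixture(paper_examples_model(), dir, "worked-examples", formats)
}

#' Write the synthetic family-domain ("people") ontology
#'
#' A small teaching-style ontology about people, families and pets: 13
#' classes, 8 properties, 9 individuals, with at least one axiom of each of
#' the 14 supported types (11 SubClassOf and 4 ObjectPropertyDomain axioms
#' among them). Synthetic: built in code to honor those published counts,
#' not a copy of any distributed ontology.
#'
#' @inheritParams write_paper_examples
#' @return Named character vector of written paths.
#' @export
write_people_ontology <- function(dir, formats = c("turtle", "rdfxml")) {
  formats <- match.arg(formats, names(FIXTURE_WRITERS), several.ok = TRUE)
  write_fixture(people_model(), dir, "people", formats)
}

#' Simulate expert ratings
#'
#' Synthetic stand-in for expert review of verbalization records. Rater 1
#' draws scores from fixed categorical distributions (clarity
#' P(1,2,3) = (.80,.15,.05), nl_fidelity P(yes) = .90, domain fidelity
#' P(1,2,3) = (.85,.10,.05)); each further rater copies rater 1 and, per
#' dimension and item, replaces the score with a *different* admissible
#' value with probability `disagreement_rate` — so expected exact-match
#' agreement is exactly `100 * (1 - disagreement_rate)`.
#'
#' @param records Verbalization records (tibble with `item_id`) or a
#'   character vector of item ids.
#' @param n_raters Number of raters (>= 1).
#' @param disagreement_rate Per-dimension perturbation probability in
#'   \[0, 1\].
#' @param seed Integer seed; same seed, same ratings.
#' @return A rating tibble (`item_id`, `rater_id`, `clarity`, `nl_fidelity`,
#'   `domain_fidelity`).
#' @export
simulate_ratings <- function(records, n_raters = 2L, disagreement_rate = 0.1,
                             seed = 1L) {
  stopifnot(n_raters >= 1L, disagreement_rate >= 0, disagreement_rate <= 1)
  item_ids <- if (is.character(records)) records else records$item_id
  n <- length(item_ids)
  stopifnot(n >= 1L)
  set.seed(seed)
  base <- tibble::tibble(
    item_id = item_ids,
    rater_id = "r1",
    clarity = sample(1:3, n, replace = TRUE, prob = c(0.80, 0.15, 0.05)),
    nl_fidelity = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.90, 0.10)),
    domain_fidelity = sample(1:3, n, replace = TRUE, prob = c(0.85, 0.10, 0.05))
  )
  out <- list(base)
  perturb_123 <- function(x, hit) {
    ifelse(hit, vapply(x, function(v) sample(setdiff(1:3, v), 1L), 0L), x)
  }
  for (r in seq_len(n_raters - 1L) + 1L) {
    rr <- base
    rr$rater_id <- paste0("r", r)
    rr$clarity <- perturb_123(rr$clarity, stats::runif(n) < disagreement_rate)
    flip <- stats::runif(n) < disagreement_rate
    rr$nl_fidelity <- ifelse(flip, ifelse(rr$nl_fidelity == "yes", "no", "yes"),
                             rr$nl_fidelity)
    rr$domain_fidelity <- perturb_123(rr$domain_fidelity,
                                      stats::runif(n) < disagreement_rate)
    out[[r]] <- rr
  }
  dplyr::bind_rows(out)
}
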