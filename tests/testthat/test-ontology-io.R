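# Loading OWL 2 ontologies from the four supported serializations into the
# axiom model.

test_that("all four serializations of the same ontology load identically", {
  fmts <- c("turtle", "rdfxml", "owlxml", "functional")
  for (paths in list(examples_path, people_path)) {
    sets <- lapply(fmts, function(f) load_ontology(paths(f)))
    keys <- lapply(sets, function(s) vapply(s$axioms, axiom_key, ""))
    for (i in 2:4) {
      expect_identical(keys[[i]], keys[[1]])
      expect_identical(sets[[i]]$entities, sets[[1]]$entities)
    }
    # downstream records identical too (format independence end to end)
    recs <- lapply(sets, verbalize_all)
    for (i in 2:4) expect_identical(recs[[i]], recs[[1]])
  }
})

test_that("the worked-example fixture loads with its one unlabeled entity", {
  ont <- load_ontology(examples_path())
  expect_s3_class(ont, "owl_axiom_set")
  expect_length(ont$axioms, 4L)
  expect_identical(unique(vapply(ont$axioms, `[[`, "", "type")), "SubClassOf")
  ents <- entity_table(ont)
  expect_identical(sum(is.na(ents$label)), 1L)
  unlabeled <- ents$iri[is.na(ents$label)]
  expect_match(unlabeled, "IAO_0000032")
  # labeled class entities from the first axiom are present with their labels
  expect_true("human subject" %in% ents$label)
  expect_true("human subject unable to give informed consent" %in% ents$label)
})

test_that("count_by_type matches the fixture's known composition", {
  counts <- count_by_type(load_ontology(people_path()))
  expect_identical(counts$n[counts$axiom_type == "SubClassOf"], 11L)
  expect_identical(counts$n[counts$axiom_type == "ObjectPropertyDomain"], 4L)
  expect_setequal(counts$axiom_type, owl_supported_types())
  expect_identical(sum(counts$n), 40L)

  counts_ex <- count_by_type(load_ontology(examples_path()))
  expect_identical(counts_ex, tibble::tibble(axiom_type = "SubClassOf", n = 4L))
})

test_that("an empty ontology document loads as zero axioms, not an error", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "<http://example.org/empty> a owl:Ontology ."
  ), path)
  ont <- load_ontology(path)
  expect_length(ont$axioms, 0L)
  expect_identical(nrow(entity_table(ont)), 0L)
  expect_identical(count_by_type(ont),
                   tibble::tibble(axiom_type = character(), n = integer()))
})

test_that("unreadable and unparseable inputs produce informative errors", {
  expect_error(load_ontology(file.path(tempdir(), "no-such-file.ttl")),
               "cannot read ontology file")
  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines("@prefix broken", bad)
  expect_error(load_ontology(bad), "failed to parse.*turtle")
  badxml <- withr::local_tempfile(fileext = ".owl")
  writeLines("<rdf:RDF <<<", badxml)
  expect_error(load_ontology(badxml, format = "rdfxml"), "failed to parse")
})

test_that("unsupported axiom types are counted and skipped, never returned", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/x#> .",
    "ex:A a owl:Class . ex:B a owl:Class .",
    "ex:p a owl:ObjectProperty . ex:q a owl:ObjectProperty .",
    "ex:A rdfs:subClassOf ex:B .",
    "ex:p rdfs:subPropertyOf ex:q .",
    "ex:p a owl:TransitiveProperty .",
    "ex:p owl:inverseOf ex:q ."
  ), path)
  ont <- load_ontology(path)
  expect_length(ont$axioms, 1L)
  expect_identical(sum(ont$unsupported), 3L)
  expect_setequal(names(ont$unsupported),
                  c("SubObjectPropertyOf", "TransitiveObjectProperty",
                    "InverseObjectProperties"))
})

test_that("label conflicts resolve to the lexicographically smallest value", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/x#> .",
    "ex:A a owl:Class . ex:B a owl:Class .",
    "ex:A rdfs:label \"zebra name\" .",
    "ex:A rdfs:label \"aardvark name\" .",
    "ex:A rdfs:subClassOf ex:B ."
  ), path)
  ont <- load_ontology(path)
  ents <- entity_table(ont)
  expect_identical(ents$label[ents$iri == "http://example.org/x#A"], "aardvark name")
})

test_that("every IRI referenced by an axiom appears in the entity index", {
  ont <- load_ontology(people_path())
  refd <- unique(vapply(
    unlist(lapply(ont$axioms, verbowl:::axiom_refs), recursive = FALSE),
    `[[`, "", "iri"))
  expect_true(all(refd %in% ont$entities$iri))
})

test_that("no label is invented for entities the file does not label", {
  ont <- load_ontology(examples_path())
  ents <- entity_table(ont)
  iao <- ents[grepl("IAO_0000032", ents$iri), ]
  expect_true(is.na(iao$label))
  # and the sentence built from it uses the IRI-fragment fallback wording
  rec <- verbalize_all(ont)
  expect_true(any(grepl("iao 0000032", rec$sentence, fixed = TRUE)))
})

test_that("repeated loads of one file are identical", {
  a <- load_ontology(people_path())
  b <- load_ontology(people_path())
  expect_identical(verbalize_all(a), verbalize_all(b))
})

test_that("owl:imports is followed only on request and only for local files", {
  d <- withr::local_tempdir()
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/x#> .",
    "ex:C a owl:Class . ex:D a owl:Class .",
    "ex:C rdfs:subClassOf ex:D ."
  ), file.path(d, "imported.ttl"))
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ex: <http://example.org/x#> .",
    "<http://example.org/main> a owl:Ontology ;",
    "  owl:imports <imported.ttl> .",
    "ex:A a owl:Class . ex:B a owl:Class .",
    "ex:A rdfs:subClassOf ex:B ."
  ), file.path(d, "main.ttl"))
  plain <- load_ontology(file.path(d, "main.ttl"))
  expect_length(plain$axioms, 1L)
  merged <- load_ontology(file.path(d, "main.ttl"), follow_imports = TRUE)
  expect_length(merged$axioms, 2L)
})

test_that("the Turtle and RDF/XML readers agree with an independent RDF parser", {
  # rdflib (Python) as the independent oracle: same triple count, and the
  # same set of fully-named (non-blank) triples
  for (fmt in c("turtle", "rdfxml")) {
    path <- people_path(fmt)
    script <- paste0(
      "import rdflib,sys\n",
      "g = rdflib.Graph()\n",
      "g.parse(sys.argv[1], format='", if (fmt == "turtle") "turtle" else "xml", "')\n",
      "named = sorted(f'{s} {p} {o}' for s, p, o in g",
      " if not isinstance(s, rdflib.BNode) and not isinstance(o, rdflib.BNode))\n",
      "print(len(g))\n",
      "for t in named: print(t)\n"
    )
    out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                   stdout = TRUE)
    oracle_total <- as.integer(out[[1L]])
    oracle_named <- out[-1L]

    text <- readChar(path, file.info(path)$size)
    tr <- if (fmt == "turtle") {
      verbowl:::parse_turtle(text)$triples
    } else {
      verbowl:::parse_rdfxml(xml2::read_xml(text))$triples
    }
    expect_identical(nrow(tr), oracle_total)
    named <- tr[!startsWith(tr$s, "_:") & tr$o_kind != "bnode", ]
    ours <- sort(paste(named$s, named$p, named$o))
    expect_identical(ours, sort(oracle_named))
  }
})
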