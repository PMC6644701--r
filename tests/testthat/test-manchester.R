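# Manchester rendering and the renderer/parser round trip.

test_that("renderings use the standard keywords and CURIE policy", {
  ont <- load_ontology(examples_path())
  m <- vapply(ont$axioms, render_manchester, "", axset = ont)
  expect_true("ICO:0000062 SubClassOf: ICO:0000073" %in% m)
  expect_true("ICO:0000171 SubClassOf: IAO:0000136 some ICO:0000064" %in% m)

  lab <- vapply(ont$axioms, render_manchester, "", name_policy = "label", axset = ont)
  expect_true(paste0("'answer option text entity' SubClassOf: ",
                     "'is about' some 'study requiring informed consent'") %in% lab)
  # an unlabeled entity falls back to its CURIE even under the label policy
  expect_true(any(grepl("IAO:0000032", lab, fixed = TRUE)))
})

test_that("an IRI with no matching prefix renders in angle brackets", {
  ax <- ax_subclass(ce_named("http://elsewhere.example/vocab/Thing1"),
                    ce_named("http://elsewhere.example/vocab/Thing2"))
  m <- render_manchester(ax)
  expect_identical(m, paste("<http://elsewhere.example/vocab/Thing1>",
                            "SubClassOf:",
                            "<http://elsewhere.example/vocab/Thing2>"))
})

test_that("a named class alone renders as its name with no keywords", {
  ont <- load_ontology(examples_path())
  expect_identical(
    verbowl:::m_expr(ce_named("http://purl.obolibrary.org/obo/ICO_0000073"),
                     "curie", ont),
    "ICO:0000073")
})

test_that("distinct axioms render to distinct strings on the fixtures", {
  for (path in c(examples_path(), people_path())) {
    ont <- load_ontology(path)
    for (pol in c("curie", "label")) {
      m <- vapply(ont$axioms, render_manchester, "", name_policy = pol, axset = ont)
      expect_identical(anyDuplicated(m), 0L)
    }
  }
})

test_that("every fixture rendering re-parses to a logically identical axiom", {
  for (path in c(examples_path(), people_path())) {
    ont <- load_ontology(path)
    for (pol in c("curie", "label")) {
      for (ax in ont$axioms) {
        m <- render_manchester(ax, name_policy = pol, axset = ont)
        back <- parse_manchester(m, ont)
        expect_identical(axiom_key(back), axiom_key(ax))
      }
    }
  }
})

test_that("the parser honors Manchester operator precedence", {
  ont <- load_ontology(people_path())
  p <- function(x) paste0("http://example.org/people#", x)
  # and binds tighter than or
  got <- parse_manchester("peo:Man and peo:Adult or peo:Woman SubClassOf: peo:Person", ont)
  want <- ax_subclass(ce_or(ce_and(ce_named(p("Man")), ce_named(p("Adult"))),
                            ce_named(p("Woman"))),
                      ce_named(p("Person")))
  expect_identical(axiom_key(got), axiom_key(want))
  # parentheses override
  got2 <- parse_manchester("peo:Man and (peo:Adult or peo:Woman) SubClassOf: peo:Person", ont)
  want2 <- ax_subclass(ce_and(ce_named(p("Man")),
                              ce_or(ce_named(p("Adult")), ce_named(p("Woman")))),
                       ce_named(p("Person")))
  expect_identical(axiom_key(got2), axiom_key(want2))
  # restriction filler recursion with negation
  got3 <- parse_manchester("peo:Person SubClassOf: peo:hasPet some (not peo:Cat)", ont)
  want3 <- ax_subclass(ce_named(p("Person")),
                       ce_some(p("hasPet"), ce_not(ce_named(p("Cat")))))
  expect_identical(axiom_key(got3), axiom_key(want3))
})
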