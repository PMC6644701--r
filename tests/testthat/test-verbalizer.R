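# Sentence generation: reference sentences, recursion, styles, totality.

test_that("the worked-example fixture reproduces its reference sentences byte-exactly", {
  rec <- verbalize_all(load_ontology(examples_path()))
  expect_identical(rec$sentence, GOLDEN_EXPLICIT)
  # unlabeled-entity fallback is flagged on the sentence that used it
  expect_identical(rec$flags[grepl("iao 0000032", rec$sentence)], "unlabeled_entity")
  expect_identical(unique(rec$flags[!grepl("iao 0000032", rec$sentence)]), "")
})

test_that("compact style rewrites only the copular existential construction", {
  explicit <- verbalize_all(load_ontology(examples_path()))
  compact <- verbalize_all(load_ontology(examples_path()), style = "compact")
  differs <- explicit$sentence != compact$sentence
  expect_identical(sum(differs), 1L)
  expect_identical(compact$sentence[differs], GOLDEN_COMPACT_VARIANT)
  expect_identical(sub(" is something that is ", " is ", explicit$sentence[differs]),
                   compact$sentence[differs])

  # on the family fixture the only existential uses a possessive property,
  # so the two styles agree everywhere
  pe <- people_path()
  expect_identical(verbalize_all(load_ontology(pe), style = "compact")$sentence,
                   verbalize_all(load_ontology(pe))$sentence)
})

test_that("class expressions verbalize by position", {
  wd <- "http://example.org/t#WeekDay"
  lex <- stats::setNames(list(lexicalize(wd, "week day")), wd)
  expect_identical(verbalize_class_expr(ce_named(wd), "predicate_np", lex),
                   "a week day")
  expect_identical(verbalize_class_expr(ce_named(wd), "subject", lex),
                   "every week day")
  expect_identical(verbalize_class_expr(ce_named(wd), "relative_clause", lex),
                   "that is a week day")

  about <- "http://example.org/t#isAbout"
  study <- "http://example.org/t#Study"
  lex2 <- stats::setNames(
    list(lexicalize(about, "is about", "object_property"),
         lexicalize(study, "study requiring informed consent")),
    c(about, study))
  expect_identical(
    verbalize_class_expr(ce_some(about, ce_named(study)), "predicate_np", lex2),
    "something that is about a study requiring informed consent")
})

test_that("nested existential restrictions recurse", {
  p <- "http://example.org/t#isAbout"
  q <- "http://example.org/t#isPartOf"
  d <- "http://example.org/t#Study"
  lex <- stats::setNames(
    list(lexicalize(p, "is about", "object_property"),
         lexicalize(q, "is part of", "object_property"),
         lexicalize(d, "study")),
    c(p, q, d))
  got <- verbalize_class_expr(ce_some(p, ce_some(q, ce_named(d))),
                              "predicate_np", lex)
  expect_identical(got, "something that is about something that is part of a study")
})

test_that("boolean class expressions verbalize", {
  a <- "http://example.org/t#Man"; b <- "http://example.org/t#Driver"
  lex <- stats::setNames(list(lexicalize(a, "man"), lexicalize(b, "driver")),
                         c(a, b))
  expect_identical(verbalize_class_expr(ce_and(ce_named(a), ce_named(b)),
                                        "predicate_np", lex),
                   "a man and a driver")
  expect_identical(verbalize_class_expr(ce_or(ce_named(a), ce_named(b)),
                                        "predicate_np", lex),
                   "a man or a driver")
  expect_identical(verbalize_class_expr(ce_not(ce_named(a)), "predicate_np", lex),
                   "not a man")
  # complex left-hand side reads as "everything that ..."
  rec <- verbalize_axiom(
    ax_subclass(ce_and(ce_named(a), ce_named(b)), ce_named(a)), lex)
  expect_identical(rec$sentence, "everything that is a man and a driver is a man")
})

test_that("every family-fixture axiom verbalizes without a fallback", {
  ont <- load_ontology(people_path())
  rec <- verbalize_all(ont)
  expect_identical(nrow(rec), length(ont$axioms))
  expect_false(any(grepl("generic_fallback", rec$flags)))
  expect_false(any(grepl("unlabeled_entity", rec$flags)))
  # sentence well-formedness: non-empty, single-line, single-spaced, no period
  expect_true(all(nzchar(rec$sentence)))
  expect_false(any(grepl("\n|  ", rec$sentence)))
  expect_false(any(grepl("\\.$", rec$sentence)))
  # one record per axiom and per-type totals conserved
  counts <- count_by_type(ont)
  rec_counts <- table(rec$axiom_type)
  expect_identical(as.integer(rec_counts[counts$axiom_type]), counts$n)
})

test_that("each axiom type uses its committed template", {
  rec <- verbalize_all(load_ontology(people_path()))
  by_type <- split(rec$sentence, rec$axiom_type)
  expect_true("every pet owner is something that has an animal as pet and vice versa"
              %in% by_type$EquivalentClasses)
  expect_true("no man is a woman" %in% by_type$DisjointClasses)
  expect_true("Alice is a woman" %in% by_type$ClassAssertion)
  expect_true("everything that knows something is a person"
              %in% by_type$ObjectPropertyDomain)
  expect_true("everything that something has as child is a person"
              %in% by_type$ObjectPropertyRange)
  expect_true("everything that has an age is a person" %in% by_type$DataPropertyDomain)
  expect_true("every age is an integer value" %in% by_type$DataPropertyRange)
  expect_true("if X has Y as spouse then Y has X as spouse"
              %in% by_type$SymmetricObjectProperty)
  expect_true("everything has at most one spouse" %in% by_type$FunctionalObjectProperty)
  expect_true("everything has at most one age" %in% by_type$FunctionalDataProperty)
  expect_true("Bob knows Alice" %in% by_type$ObjectPropertyAssertion)
  expect_true("Alice is parent of Carol" %in% by_type$ObjectPropertyAssertion)
  expect_true("the age of Alice is 34" %in% by_type$DataPropertyAssertion)
  expect_true("Alice and Bob are different" %in% by_type$DifferentIndividuals)
})

test_that("constructors outside the supported inventory fall back generically", {
  a <- "http://example.org/t#Car"
  lex <- stats::setNames(list(lexicalize(a, "car")), a)
  rec <- verbalize_axiom(ax_subclass(ce_named(a), ce_other("hasWheel min 4 Wheel")), lex)
  expect_true(grepl("hasWheel min 4 Wheel", rec$sentence, fixed = TRUE))
  expect_true("generic_fallback" %in% rec$flags)
})

test_that("verbalize_all is a pure function of its inputs", {
  ont <- load_ontology(people_path())
  expect_identical(verbalize_all(ont), verbalize_all(ont))
  expect_identical(verbalize_all(ont, style = "compact"),
                   verbalize_all(ont, style = "compact"))
})
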