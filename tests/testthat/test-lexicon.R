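# Lexicalization and morphology.

test_that("lexicalization uses labels verbatim and IRI fragments as fallback", {
  lab <- lexicalize("http://example.org/x#HS", "human subject")
  expect_identical(lab$tokens, c("human", "subject"))
  expect_identical(lab$source, "label")

  iao <- lexicalize("http://purl.obolibrary.org/obo/IAO_0000032", NA)
  expect_identical(iao$tokens, c("iao", "0000032"))
  expect_identical(iao$source, "iri_fragment")

  camel <- lexicalize("http://example.org/people#HappyPerson", NA)
  expect_identical(camel$tokens, c("happy", "person"))

  # letter case of label tokens is preserved
  sat <- lexicalize("http://purl.obolibrary.org/obo/TEO_0000048", "Saturday")
  expect_identical(sat$tokens, "Saturday")

  # IRI with no usable local fragment: whole IRI as one token, flagged
  bare <- lexicalize("http://example.org/x#", NA)
  expect_true(bare$flagged)
  expect_length(bare$tokens, 1L)
})

test_that("distinct unlabeled IRIs lexicalize to distinct surfaces", {
  iris <- c(
    "http://purl.obolibrary.org/obo/IAO_0000032",
    "http://purl.obolibrary.org/obo/IAO_0000136",
    "http://purl.obolibrary.org/obo/ICO_0000062",
    "http://example.org/people#HappyPerson",
    "http://example.org/people#hasChild"
  )
  surfaces <- vapply(iris, function(i) paste(lexicalize(i, NA)$tokens, collapse = " "), "")
  expect_identical(anyDuplicated(surfaces), 0L)
})

test_that("property labels classify by their conventional prefixes", {
  expect_identical(classify_property(c("is", "about"))$form, "copular")
  expect_identical(classify_property(c("is", "realized", "in"))$form, "copular")
  expect_identical(classify_property(c("has", "child"))$form, "possessive")
  expect_identical(classify_property(c("have", "part"))$form, "possessive")
  expect_identical(classify_property("precedes")$form, "plain_verb")
  # single-token labels are plain verbs even when the token is "has"
  expect_identical(classify_property("has")$form, "plain_verb")
})

test_that("lemmatization never reproduces the suffix-stripping defect", {
  # regression set: each word is already a lemma and must survive unchanged
  for (w in c("data", "analysis", "species", "status")) {
    expect_identical(lemmatize_token(w), w)
  }
  expect_identical(lemmatize_token("is"), "be")
  expect_identical(lemmatize_token("has"), "have")
  expect_identical(lemmatize_token("studies"), "study")
  expect_identical(lemmatize_token("children"), "child")
})

test_that("lemmatize inverts pluralize on regular nouns", {
  set.seed(42)
  words <- sample(REGULAR_NOUNS, 100L)
  for (w in words) {
    expect_identical(lemmatize_token(pluralize_noun(w)), w)
  }
})

test_that("third-person-singular inflection matches the frozen verb table", {
  for (lemma in names(VERB_3SG_TABLE)) {
    expect_identical(verb_3sg(lemma), unname(VERB_3SG_TABLE[[lemma]]))
  }
  # and "precedes" survives the classify -> lemmatize -> inflect loop
  expect_identical(verb_3sg(lemmatize_token("precedes")), "precedes")
})

test_that("article selection handles vowels, consonants and pronunciation exceptions", {
  expect_identical(realize_article("iao"), "an")
  expect_identical(realize_article("human"), "a")
  expect_identical(realize_article("hour"), "an")
  expect_identical(realize_article("honest"), "an")
  expect_identical(realize_article("university"), "a")
  expect_identical(realize_article("one"), "a")
  expect_identical(realize_article("integer"), "an")
  expect_identical(realize_article("week"), "a")
})

test_that("a user lexicon CSV overrides automatic lexicalization", {
  ont <- load_ontology(people_path())
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "iri,surface,phrase_kind",
    "http://example.org/people#Dog,canine companion,noun_phrase"
  ), csv)
  rec <- verbalize_all(ont, lexicon_csv = csv)
  expect_true(any(grepl("canine companion", rec$sentence, fixed = TRUE)))
  expect_false(any(grepl("\\bdog\\b", rec$sentence)))
})
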