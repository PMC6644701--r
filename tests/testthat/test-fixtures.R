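# Fixture generators: published-count compliance and reproducibility.

test_that("the family fixture honors its published composition", {
  ont <- load_ontology(people_path())
  ents <- entity_table(ont)
  expect_identical(sum(ents$kind == "class"), 13L)
  expect_identical(sum(ents$kind %in% c("object_property", "data_property")), 8L)
  expect_identical(sum(ents$kind == "named_individual"), 9L)
  expect_setequal(count_by_type(ont)$axiom_type, owl_supported_types())
})

test_that("the worked-example fixture contains exactly its four axioms", {
  ont <- load_ontology(examples_path())
  expect_identical(count_by_type(ont),
                   tibble::tibble(axiom_type = "SubClassOf", n = 4L))
  expect_identical(sum(is.na(entity_table(ont)$label)), 1L)
})

test_that("fixture files regenerate bit-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    write_paper_examples(d, formats = c("turtle", "rdfxml", "owlxml", "functional"))
    write_people_ontology(d, formats = c("turtle", "rdfxml", "owlxml", "functional"))
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("simulated ratings are seed-reproducible and respect their rate", {
  ids <- sprintf("i%03d", 1:50)
  a <- simulate_ratings(ids, n_raters = 3, disagreement_rate = 0.3, seed = 99)
  b <- simulate_ratings(ids, n_raters = 3, disagreement_rate = 0.3, seed = 99)
  expect_identical(a, b)
  expect_identical(sort(unique(a$rater_id)), c("r1", "r2", "r3"))
  expect_identical(nrow(a), 150L)

  # zero disagreement: all raters identical, agreement 100 on every dimension
  z <- simulate_ratings(ids, n_raters = 2, disagreement_rate = 0, seed = 1)
  for (dim in c("clarity", "nl_fidelity", "domain_fidelity")) {
    expect_identical(percent_agreement(z[z$rater_id == "r1", ],
                                       z[z$rater_id == "r2", ], dim), 100)
  }

  # rate 0.5 at n = 1000: agreement within the 99% binomial interval of 50%
  ids2 <- sprintf("i%04d", 1:1000)
  h <- simulate_ratings(ids2, n_raters = 2, disagreement_rate = 0.5, seed = 2)
  agree <- percent_agreement(h[h$rater_id == "r1", ], h[h$rater_id == "r2", ],
                             "domain_fidelity")
  half <- 100 * 2.576 * sqrt(0.25 / 1000)
  expect_gt(agree, 50 - half)
  expect_lt(agree, 50 + half)

  expect_error(simulate_ratings(ids, n_raters = 0), "n_raters")
})

test_that("perturbed scores always differ from the original", {
  ids <- sprintf("i%03d", 1:300)
  rt <- simulate_ratings(ids, n_raters = 2, disagreement_rate = 1, seed = 4)
  r1 <- rt[rt$rater_id == "r1", ]
  r2 <- rt[rt$rater_id == "r2", ]
  expect_true(all(r1$clarity != r2$clarity))
  expect_true(all(r1$nl_fidelity != r2$nl_fidelity))
  expect_true(all(r1$domain_fidelity != r2$domain_fidelity))
})
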