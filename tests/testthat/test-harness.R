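# Rating harness: sheets, agreement, summaries, Spearman correlation.

# small synthetic rating table: k raters over the family-fixture sentences
demo_ratings <- function(n_raters = 2, rate = 0.1, seed = 11) {
  rec <- verbalize_all(load_ontology(people_path()))
  list(records = rec,
       ratings = simulate_ratings(rec, n_raters = n_raters,
                                  disagreement_rate = rate, seed = seed))
}

test_that("rating sheets have the reviewer layout", {
  rec <- verbalize_all(load_ontology(examples_path()))
  path <- withr::local_tempfile(fileext = ".csv")
  sheet <- make_rating_sheet(rec[1:3, ], path, raters = 2)
  expect_identical(dim(sheet), c(3L, 10L))
  expect_identical(names(sheet)[1:4], c("item_id", "axiom_type", "logic", "nl_sentence"))
  expect_identical(names(sheet)[5:7],
                   c("clarity_r1", "nl_fidelity_r1", "domain_fidelity_r1"))
  on_disk <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(on_disk), 3L)
  # a row pairs the axiom type with its reference sentence
  expect_true(any(on_disk$axiom_type == "SubClassOf" &
                    on_disk$nl_sentence == GOLDEN_EXPLICIT[[1]]))

  expect_error(make_rating_sheet(rec[0, ], withr::local_tempfile()), "zero records")
})

test_that("percent agreement is the exact-match proportion", {
  r <- tibble::tibble(item_id = paste0("i", 1:4), rater_id = "a",
                      clarity = c(1L, 2L, 1L, 3L),
                      nl_fidelity = c("yes", "yes", "no", "yes"),
                      domain_fidelity = c(1L, 1L, 2L, 1L))
  expect_identical(percent_agreement(r, r, "clarity"), 100)
  r2 <- r; r2$rater_id <- "b"; r2$clarity[2] <- 3L
  expect_identical(percent_agreement(r, r2, "clarity"), 75)
  expect_identical(percent_agreement(r, r2, "nl_fidelity"), 100)
  # mismatched item sets are a contract violation naming the difference
  r3 <- r2[-1, ]
  expect_error(percent_agreement(r, r3, "clarity"), "i1")
})

test_that("simulated disagreement lands at its binomial expectation", {
  ids <- sprintf("i%03d", 1:200)
  rt <- simulate_ratings(ids, n_raters = 2, disagreement_rate = 0.14, seed = 5)
  r1 <- rt[rt$rater_id == "r1", ]
  r2 <- rt[rt$rater_id == "r2", ]
  agree <- percent_agreement(r1, r2, "clarity")
  # 99% binomial CI around 86% at n = 200
  half <- 100 * 2.576 * sqrt(0.86 * 0.14 / 200)
  expect_gt(agree, 86 - half)
  expect_lt(agree, 86 + half)
})

test_that("pooled summaries follow their definitions", {
  d <- demo_ratings()
  s <- summarize_ratings(d$ratings)
  expect_s3_class(s, "owl_eval_summary")
  expect_true(s$clarity_mean >= 1 && s$clarity_mean <= 3)
  expect_true(s$domain_fidelity_mean >= 1 && s$domain_fidelity_mean <= 3)
  expect_true(s$nl_fidelity_pct_yes >= 0 && s$nl_fidelity_pct_yes <= 100)
  # %yes is over all votes, not per-item means
  expect_identical(s$nl_fidelity_pct_yes, 100 * mean(d$ratings$nl_fidelity == "yes"))
  # row order does not matter
  shuffled <- d$ratings[sample(nrow(d$ratings)), ]
  expect_equal(glance(summarize_ratings(shuffled)), glance(s))
  # tidy/glance surfaces
  expect_identical(nrow(tidy(s)), 3L)
  expect_identical(nrow(glance(s)), 1L)
})

test_that("degenerate and monotone inputs give the documented rho behavior", {
  one <- tibble::tibble(item_id = "i1", rater_id = "a", clarity = 2L,
                        nl_fidelity = "yes", domain_fidelity = 1L)
  s <- summarize_ratings(one)
  expect_identical(s$clarity_mean, 2)
  expect_identical(s$domain_fidelity_mean, 1)
  expect_identical(s$nl_fidelity_pct_yes, 100)
  expect_false(s$spearman_defined)
  expect_true(is.na(s$spearman_rho))

  # clarity identical to domain fidelity over 20 items: rho exactly 1
  mono <- tibble::tibble(
    item_id = sprintf("i%02d", 1:20), rater_id = "a",
    clarity = rep(1:3, length.out = 20)[sample(20)],
    nl_fidelity = "yes",
    domain_fidelity = 1L
  )
  mono$domain_fidelity <- mono$clarity
  s2 <- summarize_ratings(mono)
  expect_identical(s2$spearman_rho, 1)
})

test_that("rho matches a brute-force rank computation and is monotone-invariant", {
  d <- demo_ratings(n_raters = 3, rate = 0.2, seed = 3)
  s <- summarize_ratings(d$ratings)
  per_item <- aggregate(cbind(clarity, domain_fidelity) ~ item_id,
                        data = d$ratings, FUN = mean)
  expect_true(s$spearman_defined)
  expect_equal(s$spearman_rho,
               brute_spearman(per_item$clarity, per_item$domain_fidelity),
               tolerance = 1e-12)
  # invariance under a strictly monotone transform of either vector
  expect_equal(brute_spearman(exp(per_item$clarity), per_item$domain_fidelity^3),
               s$spearman_rho, tolerance = 1e-12)
})

test_that("per-type summaries recombine to the pooled summary", {
  d <- demo_ratings(seed = 17)
  s <- summarize_ratings(d$ratings)
  bt <- summarize_by_type(d$ratings, d$records)
  expect_setequal(bt$axiom_type, unique(d$records$axiom_type))
  expect_identical(sum(bt$n_items), s$n_items)
  expect_equal(sum(bt$clarity_mean * bt$n_items) / sum(bt$n_items), s$clarity_mean)
  expect_equal(sum(bt$domain_fidelity_mean * bt$n_items) / sum(bt$n_items),
               s$domain_fidelity_mean)
  # %yes recombines weighted by vote counts; every item here has equal votes
  expect_equal(sum(bt$nl_fidelity_pct_yes * bt$n_items) / sum(bt$n_items),
               s$nl_fidelity_pct_yes)

  # groups with no ratings are omitted
  sub <- d$ratings[d$ratings$item_id %in%
                     d$records$item_id[d$records$axiom_type == "SubClassOf"], ]
  bt2 <- summarize_by_type(sub, d$records)
  expect_identical(bt2$axiom_type, "SubClassOf")
  expect_identical(sum(bt2$n_items), length(unique(sub$item_id)))
})

test_that("a rater agrees with itself completely on every dimension", {
  d <- demo_ratings(n_raters = 1)
  r1 <- d$ratings
  for (dim in c("clarity", "nl_fidelity", "domain_fidelity")) {
    expect_identical(percent_agreement(r1, r1, dim), 100)
  }
  # single-rater summaries have undefined agreement but defined means
  s <- summarize_ratings(r1)
  expect_true(all(is.na(s$agreement)))
  expect_false(is.na(s$clarity_mean))
})
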