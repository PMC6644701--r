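# Expert-evaluation harness: rating sheets, rating ingestion, percent
# agreement between raters, pooled and per-axiom-type summaries, and the
# clarity-vs-domain-fidelity Spearman correlation.
#
# Rating scales: clarity in {1,2,3} (1 = clear; 2 = clear but the axiom
# introduces ambiguity; 3 = not interpretable); nl_fidelity in {yes,no}
# (does the sentence express the axiom's logic); domain_fidelity in {1,2,3}
# (1 = reviewer agrees with the axiom; 2 = disagrees/uncertain about
# concepts or relationships; 3 = about both).

RATING_COLS <- c("item_id", "rater_id", "clarity", "nl_fidelity", "domain_fidelity")
RATING_DIMENSIONS <- c("clarity", "nl_fidelity", "domain_fidelity")

#' Write a rating sheet for expert review
#'
#' Lays out verbalization records the way reviewers score them: the first
#' columns carry the axiom type, the logic (Manchester rendering) and the
#' sentence; then, per configured rater, empty `clarity`, `nl_fidelity` and
#' `domain_fidelity` columns to fill in.
#'
#' @param records A tibble from [verbalize_all()] (needs `item_id`,
#'   `axiom_type`, `manchester`, `sentence`).
#' @param path Output CSV path.
#' @param raters Number of raters (>= 1).
#' @return The sheet tibble, invisibly; the CSV is written to `path`.
#' @export
make_rating_sheet <- function(records, path, raters = 2L) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot write a rating sheet for zero records", call. = FALSE)
  }
  stopifnot(raters >= 1L)
  sheet <- tibble::tibble(
    item_id = records$item_id,
    axiom_type = records$axiom_type,
    logic = records$manchester,
    nl_sentence = records$sentence
  )
  for (r in seq_len(raters)) {
    for (dim in RATING_DIMENSIONS) {
      sheet[[paste0(dim, "_r", r)]] <- ""
    }
  }
  readr::write_csv(sheet, path, progress = FALSE)
  invisible(sheet)
}

#' Read a rating CSV
#'
#' Expects columns `item_id`, `rater_id`, `clarity` (1-3), `nl_fidelity`
#' (`yes`/`no`), `domain_fidelity` (1-3). Malformed rows abort with their
#' row numbers.
#'
#' @param path CSV path (or several; rows are concatenated).
#' @return A validated rating tibble.
#' @export
read_ratings <- function(path) {
  tbs <- lapply(path, function(p) {
    tb <- readr::read_csv(p, col_types = readr::cols(
      item_id = readr::col_character(),
      rater_id = readr::col_character(),
      clarity = readr::col_integer(),
      nl_fidelity = readr::col_character(),
      domain_fidelity = readr::col_integer()
    ), progress = FALSE)
    if (!all(RATING_COLS %in% names(tb))) {
      stop("rating CSV '", p, "' must have columns: ",
           paste(RATING_COLS, collapse = ", "), call. = FALSE)
    }
    bad <- which(!tb$clarity %in% 1:3 | !tb$nl_fidelity %in% c("yes", "no") |
                   !tb$domain_fidelity %in% 1:3)
    if (length(bad)) {
      stop("malformed rating rows in '", p, "': ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    tb[RATING_COLS]
  })
  dplyr::bind_rows(tbs)
}

#' Percent agreement between two raters
#'
#' The proportion (as a percentage) of items on which two raters gave an
#' identical score on one dimension. Plain exact-match agreement, no chance
#' correction.
#'
#' @param r1,r2 Rating tibbles for one rater each (same `item_id` sets).
#' @param dimension `"clarity"`, `"nl_fidelity"` or `"domain_fidelity"`.
#' @return A percentage in \[0, 100\].
#' @export
percent_agreement <- function(r1, r2, dimension = RATING_DIMENSIONS) {
  dimension <- match.arg(dimension)
  only1 <- setdiff(r1$item_id, r2$item_id)
  only2 <- setdiff(r2$item_id, r1$item_id)
  if (length(only1) || length(only2)) {
    stop("raters scored different item sets; only in first: ",
         paste(utils::head(only1, 5L), collapse = ", "),
         "; only in second: ", paste(utils::head(only2, 5L), collapse = ", "),
         call. = FALSE)
  }
  merged <- dplyr::inner_join(
    r1[, c("item_id", dimension)], r2[, c("item_id", dimension)],
    by = "item_id", suffix = c("_1", "_2")
  )
  100 * mean(merged[[paste0(dimension, "_1")]] == merged[[paste0(dimension, "_2")]])
}

# mean inter-rater agreement over all rater pairs; NA with a single rater
agreement_by_dimension <- function(ratings) {
  raters <- sort(unique(ratings$rater_id))
  out <- stats::setNames(rep(NA_real_, length(RATING_DIMENSIONS)), RATING_DIMENSIONS)
  if (length(raters) < 2L) return(out)
  pairs <- utils::combn(raters, 2L, simplify = FALSE)
  for (dim in RATING_DIMENSIONS) {
    vals <- vapply(pairs, function(pr) {
      percent_agreement(ratings[ratings$rater_id == pr[[1L]], ],
                        ratings[ratings$rater_id == pr[[2L]], ], dim)
    }, 0)
    out[[dim]] <- mean(vals)
  }
  out
}

#' Summarize ratings for one ontology
#'
#' Pools all raters' scores: clarity and domain-fidelity means and SDs are
#' computed over per-item mean scores across raters; the yes-percentage is
#' over all individual `nl_fidelity` votes; inter-rater agreement is the
#' mean pairwise exact-match percentage per dimension; and Spearman's rho
#' (tie-corrected ranks, large-sample p) correlates per-item mean clarity
#' with per-item mean domain fidelity. When either vector is constant, rho
#' is undefined and reported as `NA` with `spearman_defined = FALSE` —
#' never silently as 0.
#'
#' @param ratings A rating tibble (see [read_ratings()]).
#' @return An object of class `owl_eval_summary`; see [tidy.owl_eval_summary()]
#'   and [glance.owl_eval_summary()].
#' @export
summarize_ratings <- function(ratings) {
  stopifnot(nrow(ratings) >= 1L)
  per_item <- ratings |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(
      clarity = mean(.data$clarity),
      domain_fidelity = mean(.data$domain_fidelity),
      .groups = "drop"
    )
  rho <- spearman_clarity_domain(per_item$clarity, per_item$domain_fidelity)
  structure(
    list(
      n_items = nrow(per_item),
      n_raters = length(unique(ratings$rater_id)),
      n_ratings = nrow(ratings),
      clarity_mean = mean(per_item$clarity),
      clarity_sd = stats::sd(per_item$clarity),
      nl_fidelity_pct_yes = 100 * mean(ratings$nl_fidelity == "yes"),
      domain_fidelity_mean = mean(per_item$domain_fidelity),
      domain_fidelity_sd = stats::sd(per_item$domain_fidelity),
      agreement = agreement_by_dimension(ratings),
      spearman_rho = rho$rho,
      spearman_p = rho$p,
      spearman_defined = rho$defined
    ),
    class = "owl_eval_summary"
  )
}

spearman_clarity_domain <- function(x, y) {
  if (length(x) < 2L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' @export
print.owl_eval_summary <- function(x, ...) {
  cat("<owl_eval_summary> ", x$n_items, " items, ", x$n_raters, " raters\n", sep = "")
  cat(sprintf("  clarity          %.2f (%.2f)\n", x$clarity_mean, x$clarity_sd))
  cat(sprintf("  nl fidelity      %.0f%% yes\n", x$nl_fidelity_pct_yes))
  cat(sprintf("  domain fidelity  %.2f (%.2f)\n", x$domain_fidelity_mean,
              x$domain_fidelity_sd))
  if (!is.na(x$agreement[["clarity"]])) {
    cat(sprintf("  agreement        %.0f%% / %.0f%% / %.0f%% (clarity / nl / domain)\n",
                x$agreement[["clarity"]], x$agreement[["nl_fidelity"]],
                x$agreement[["domain_fidelity"]]))
  }
  if (isTRUE(x$spearman_defined)) {
    cat(sprintf("  spearman rho     %.2f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  } else {
    cat("  spearman rho     undefined (constant scores)\n")
  }
  invisible(x)
}

#' Tidy an evaluation summary into one row per dimension
#'
#' @param x An `owl_eval_summary`.
#' @param ... Unused.
#' @return A tibble with columns `dimension`, `mean`, `sd`, `pct_yes`,
#'   `agreement_pct`.
#' @method tidy owl_eval_summary
#' @export
tidy.owl_eval_summary <- function(x, ...) {
  tibble::tibble(
    dimension = RATING_DIMENSIONS,
    mean = c(x$clarity_mean, NA_real_, x$domain_fidelity_mean),
    sd = c(x$clarity_sd, NA_real_, x$domain_fidelity_sd),
    pct_yes = c(NA_real_, x$nl_fidelity_pct_yes, NA_real_),
    agreement_pct = unname(x$agreement[RATING_DIMENSIONS])
  )
}

#' One-row overview of an evaluation summary
#'
#' @param x An `owl_eval_summary`.
#' @param ... Unused.
#' @return A one-row tibble mirroring the per-ontology summary layout:
#'   clarity mean/sd, yes-percentage, domain mean/sd, Spearman rho and p.
#' @method glance owl_eval_summary
#' @export
glance.owl_eval_summary <- function(x, ...) {
  tibble::tibble(
    n_items = x$n_items,
    n_raters = x$n_raters,
    clarity_mean = x$clarity_mean,
    clarity_sd = x$clarity_sd,
    nl_fidelity_pct_yes = x$nl_fidelity_pct_yes,
    domain_fidelity_mean = x$domain_fidelity_mean,
    domain_fidelity_sd = x$domain_fidelity_sd,
    spearman_rho = x$spearman_rho,
    spearman_p = x$spearman_p,
    spearman_defined = x$spearman_defined
  )
}

#' Per-axiom-type rating summaries
#'
#' Groups ratings by the axiom type of their item (via the verbalization
#' records) and summarizes each group as [summarize_ratings()] does. Types
#' with no ratings are omitted.
#'
#' @param ratings A rating tibble.
#' @param records A tibble from [verbalize_all()] mapping `item_id` to
#'   `axiom_type`.
#' @return A tibble of class `owl_eval_by_type`: one row per axiom type
#'   with `n_items`, means/SDs, yes-percentage, agreement columns, rho.
#' @export
summarize_by_type <- function(ratings, records) {
  joined <- dplyr::inner_join(ratings,
                              records[, c("item_id", "axiom_type")],
                              by = "item_id")
  types <- sort(unique(joined$axiom_type))
  rows <- lapply(types, function(ty) {
    s <- summarize_ratings(joined[joined$axiom_type == ty, RATING_COLS])
    tibble::tibble(
      axiom_type = ty,
      n_items = s$n_items,
      clarity_mean = s$clarity_mean,
      clarity_sd = s$clarity_sd,
      nl_fidelity_pct_yes = s$nl_fidelity_pct_yes,
      domain_fidelity_mean = s$domain_fidelity_mean,
      domain_fidelity_sd = s$domain_fidelity_sd,
      agreement_clarity = s$agreement[["clarity"]],
      agreement_nl_fidelity = s$agreement[["nl_fidelity"]],
      agreement_domain_fidelity = s$agreement[["domain_fidelity"]],
      spearman_rho = s$spearman_rho,
      spearman_defined = s$spearman_defined
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("owl_eval_by_type", class(out))
  out
}

#' Plot per-axiom-type rating summaries
#'
#' Dot-and-error-bar chart of mean clarity and domain fidelity per axiom
#' type, the per-type assessment view.
#'
#' @param object An `owl_eval_by_type` tibble from [summarize_by_type()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot owl_eval_by_type
#' @export
autoplot.owl_eval_by_type <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("axiom_type", "clarity_mean", "clarity_sd",
                                  "domain_fidelity_mean", "domain_fidelity_sd")],
    cols = -"axiom_type",
    names_to = c("dimension", ".value"),
    names_pattern = "(clarity|domain_fidelity)_(mean|sd)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$axiom_type,
                                     color = .data$dimension)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(1, .data$mean - .data$sd),
                   xmax = pmin(3, .data$mean + .data$sd)),
      height = 0.3, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_continuous(limits = c(1, 3)) +
    ggplot2::labs(x = "mean score (1 = best, 3 = worst)", y = NULL,
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation summary
#'
#' @param object An `owl_eval_summary`.
#' @param ... Unused.
#' @return A ggplot object showing the three dimensions' pooled results.
#' @method autoplot owl_eval_summary
#' @export
autoplot.owl_eval_summary <- function(object, ...) {
  tb <- tidy(object)
  tb$label <- ifelse(is.na(tb$mean),
                     sprintf("%.0f%% yes", tb$pct_yes),
                     sprintf("%.2f (%.2f)", tb$mean, tb$sd))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$dimension,
                                   y = ifelse(is.na(.data$mean),
                                              .data$pct_yes / 50, .data$mean))) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "pooled score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
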