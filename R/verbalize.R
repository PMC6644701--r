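# Axiom verbalization: each supported axiom type has a sentence template;
# class expressions are rendered by structural recursion and realized with
# articles and verb agreement. Sentences follow the conventions of the
# evaluated outputs: single line, no sentence-initial capitalization, no
# final period, label tokens used verbatim.

join_tokens <- function(tokens) paste(tokens, collapse = " ")

# noun phrase with indefinite article: "a human subject", "an iao 0000032"
np_article <- function(tokens) {
  paste(realize_article(tokens[[1L]]), join_tokens(tokens))
}

# verbalization context: lexicon plus an accumulator for diagnostic flags
new_vctx <- function(lexicon, style = "explicit") {
  env <- new.env(parent = emptyenv())
  env$lexicon <- lexicon
  env$style <- style
  env$flags <- character()
  env
}

vctx_flag <- function(ctx, flag) {
  ctx$flags <- union(ctx$flags, flag)
}

vctx_entry <- function(ctx, iri, kind = "class") {
  entry <- lex_get(ctx$lexicon, iri, kind)
  if (entry$source == "iri_fragment") vctx_flag(ctx, "unlabeled_entity")
  entry
}

# property verb phrase, realized with a following object noun phrase:
#   copular    "is about"  + NP ->  "is about <NP>"
#   possessive "has child" + NP ->  "has <NP> as child"
#   plain      "precedes"  + NP ->  "precedes <NP>"
vp_with_object <- function(vpc, obj_np) {
  tokens <- vpc$tokens
  switch(vpc$form,
    copular = paste(join_tokens(tokens), obj_np),
    possessive = {
      rest <- tokens[-1L]
      head3 <- verb_3sg(lemmatize_token(tokens[[1L]]))
      if (length(rest)) paste(head3, obj_np, "as", join_tokens(rest))
      else paste(head3, obj_np)
    },
    plain_verb = {
      head3 <- verb_3sg(lemmatize_token(tokens[[1L]]))
      squish(paste(head3, join_tokens(tokens[-1L]), obj_np))
    }
  )
}

# property verb phrase with its object gap at the front (for range wording:
# "everything that something <vp_bare>")
vp_bare <- function(vpc) {
  tokens <- vpc$tokens
  switch(vpc$form,
    copular = join_tokens(tokens),
    possessive = {
      rest <- tokens[-1L]
      head3 <- verb_3sg(lemmatize_token(tokens[[1L]]))
      squish(paste(head3, if (length(rest)) paste("as", join_tokens(rest)) else ""))
    },
    plain_verb = {
      head3 <- verb_3sg(lemmatize_token(tokens[[1L]]))
      squish(paste(head3, join_tokens(tokens[-1L])))
    }
  )
}

# the nominal inside a data-property label: "has age" -> "age"
prop_noun <- function(vpc) {
  if (vpc$form %in% c("possessive", "copular") && length(vpc$tokens) > 1L) {
    vpc$tokens[-1L]
  } else {
    vpc$tokens
  }
}

prop_vpc <- function(ctx, iri, data = FALSE) {
  entry <- vctx_entry(ctx, iri, if (data) "data_property" else "object_property")
  classify_property(entry)
}

# noun phrase for a restriction filler (class expression, datatype, literal
# or individual IRI)
filler_np <- function(ctx, filler) {
  if (inherits(filler, "owl_datatype")) {
    name <- iri_fragment(filler$iri)
    return(paste(realize_article(name), name, "value"))
  }
  if (is_literal(filler)) return(filler$value)
  if (is.character(filler)) {
    return(join_tokens(vctx_entry(ctx, filler, "named_individual")$tokens))
  }
  ce_np(ctx, filler)
}

# verb phrase of a restriction node
ce_vp <- function(ctx, expr) {
  vpc <- prop_vpc(ctx, expr$property, data = isTRUE(expr$data))
  obj <- filler_np(ctx, expr$filler)
  switch(expr$kind,
    some_values = vp_with_object(vpc, obj),
    all_values = vp_with_object(vpc, paste("only", obj)),
    has_value = vp_with_object(vpc, obj)
  )
}

# noun-phrase rendering ("a week day", "something that is about a study ...")
ce_np <- function(ctx, expr) {
  switch(expr$kind,
    named = np_article(vctx_entry(ctx, expr$iri)$tokens),
    intersection = paste(vapply(expr$children, function(ch) ce_np(ctx, ch), ""),
                         collapse = " and "),
    union = paste(vapply(expr$children, function(ch) ce_np(ctx, ch), ""),
                  collapse = " or "),
    complement = paste("not", ce_np(ctx, expr$children[[1L]])),
    some_values = ,
    all_values = ,
    has_value = paste("something that", ce_vp(ctx, expr)),
    other = {
      vctx_flag(ctx, "generic_fallback")
      expr$manchester
    }
  )
}

# predicate rendering — the "is ..." part after a subject
ce_pred <- function(ctx, expr) {
  switch(expr$kind,
    named = ,
    intersection = ,
    union = paste("is", ce_np(ctx, expr)),
    complement = paste("is not", ce_np(ctx, expr$children[[1L]])),
    some_values = {
      vpc <- prop_vpc(ctx, expr$property, data = isTRUE(expr$data))
      if (ctx$style == "compact" && vpc$form == "copular") {
        ce_vp(ctx, expr)
      } else {
        paste("is something that", ce_vp(ctx, expr))
      }
    },
    all_values = ,
    has_value = paste("is something that", ce_vp(ctx, expr)),
    other = {
      vctx_flag(ctx, "generic_fallback")
      paste("is", expr$manchester)
    }
  )
}

# subject rendering: "every <named>" or "everything that <predicate>"
ce_subject <- function(ctx, expr) {
  if (expr$kind == "named") {
    paste("every", join_tokens(vctx_entry(ctx, expr$iri)$tokens))
  } else {
    paste("everything that", ce_pred(ctx, expr))
  }
}

#' Verbalize a class expression
#'
#' Renders a class expression as a phrase for a given syntactic position:
#' `"subject"` ("every week day" / "everything that ..."), `"predicate_np"`
#' (a noun phrase: "a week day", "something that is about a study ..."), or
#' `"relative_clause"` ("that is a week day").
#'
#' @param expr A class expression (see [class_expr]).
#' @param position One of `"subject"`, `"predicate_np"`, `"relative_clause"`.
#' @param lexicon A lexicon context from a loaded ontology ([load_ontology()]
#'   entities are used automatically by [verbalize_all()]); may be a named
#'   list of `lex_entry` objects. Missing entries fall back to IRI fragments.
#' @param style `"explicit"` (restrictions introduce "is something that") or
#'   `"compact"` (copular property restrictions drop the bridge phrase).
#' @return A character scalar phrase.
#' @export
#' @examples
#' lex <- list()
#' verbalize_class_expr(ce_named("http://example.org/WeekDay"), "predicate_np", lex)
verbalize_class_expr <- function(expr, position = c("predicate_np", "subject",
                                                    "relative_clause"),
                                 lexicon = list(), style = c("explicit", "compact")) {
  position <- match.arg(position)
  style <- match.arg(style)
  ctx <- new_vctx(lexicon, style)
  out <- switch(position,
    subject = ce_subject(ctx, expr),
    predicate_np = ce_np(ctx, expr),
    relative_clause = paste("that", ce_pred(ctx, expr))
  )
  squish(out)
}

#' Verbalize one axiom
#'
#' Applies the axiom type's sentence template, embedding recursively
#' verbalized class expressions, and returns one verbalization record.
#'
#' @param axiom An `owl_axiom`.
#' @param lexicon Named list of `lex_entry` objects (IRI-keyed); entities
#'   absent from it are lexicalized from their IRI fragment and flagged.
#' @param style `"explicit"` or `"compact"` (see [verbalize_class_expr()]).
#' @param axset Optional `owl_axiom_set` supplying the Manchester rendering
#'   prefix map.
#' @return A list with `axiom_type`, `manchester`, `sentence` and `flags`
#'   (character vector, possibly empty, drawn from `unlabeled_entity` and
#'   `generic_fallback`).
#' @export
verbalize_axiom <- function(axiom, lexicon = list(),
                            style = c("explicit", "compact"), axset = NULL) {
  style <- match.arg(style)
  stopifnot(inherits(axiom, "owl_axiom"))
  ctx <- new_vctx(lexicon, style)

  ind_name <- function(iri) join_tokens(vctx_entry(ctx, iri, "named_individual")$tokens)
  disj_subject <- function(expr) {
    if (expr$kind == "named") join_tokens(vctx_entry(ctx, expr$iri)$tokens)
    else paste("something that", ce_pred(ctx, expr))
  }

  sentence <- switch(axiom$type,
    SubClassOf = paste(ce_subject(ctx, axiom$sub), ce_pred(ctx, axiom$sup)),
    EquivalentClasses = {
      first <- axiom$exprs[[1L]]
      parts <- vapply(axiom$exprs[-1L], function(e) {
        paste(ce_subject(ctx, first), ce_pred(ctx, e), "and vice versa")
      }, "")
      paste(parts, collapse = " and ")
    },
    DisjointClasses = {
      n <- length(axiom$exprs)
      pairs <- character()
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          pairs <- c(pairs, paste("no", disj_subject(axiom$exprs[[i]]),
                                  "is", ce_np(ctx, axiom$exprs[[j]])))
        }
      }
      paste(pairs, collapse = " and ")
    },
    ClassAssertion = paste(ind_name(axiom$individual), ce_pred(ctx, axiom$expr)),
    ObjectPropertyDomain = {
      vpc <- prop_vpc(ctx, axiom$property)
      paste("everything that", vp_with_object(vpc, "something"),
            ce_pred(ctx, axiom$expr))
    },
    ObjectPropertyRange = {
      vpc <- prop_vpc(ctx, axiom$property)
      paste("everything that something", vp_bare(vpc), ce_pred(ctx, axiom$expr))
    },
    DataPropertyDomain = {
      vpc <- prop_vpc(ctx, axiom$property, data = TRUE)
      noun <- prop_noun(vpc)
      paste("everything that has", np_article(noun), ce_pred(ctx, axiom$expr))
    },
    DataPropertyRange = {
      vpc <- prop_vpc(ctx, axiom$property, data = TRUE)
      noun <- prop_noun(vpc)
      dt <- iri_fragment(axiom$datatype)
      paste("every", join_tokens(noun), "is", realize_article(dt), dt, "value")
    },
    SymmetricObjectProperty = {
      vpc <- prop_vpc(ctx, axiom$property)
      paste("if X", vp_with_object(vpc, "Y"), "then Y", vp_with_object(vpc, "X"))
    },
    FunctionalObjectProperty = {
      vpc <- prop_vpc(ctx, axiom$property)
      if (vpc$form == "possessive" && length(vpc$tokens) > 1L) {
        paste("everything has at most one", join_tokens(prop_noun(vpc)))
      } else {
        paste("everything", vp_with_object(vpc, "at most one thing"))
      }
    },
    FunctionalDataProperty = {
      vpc <- prop_vpc(ctx, axiom$property, data = TRUE)
      paste("everything has at most one", join_tokens(prop_noun(vpc)))
    },
    ObjectPropertyAssertion = {
      vpc <- prop_vpc(ctx, axiom$property)
      paste(ind_name(axiom$a), vp_with_object(vpc, ind_name(axiom$b)))
    },
    DataPropertyAssertion = {
      vpc <- prop_vpc(ctx, axiom$property, data = TRUE)
      paste("the", join_tokens(prop_noun(vpc)), "of", ind_name(axiom$a),
            "is", axiom$value$value)
    },
    DifferentIndividuals = {
      paste(paste(vapply(axiom$individuals, ind_name, ""), collapse = " and "),
            "are different")
    },
    stop("unsupported axiom type: ", axiom$type, call. = FALSE)
  )

  list(
    axiom_type = axiom$type,
    manchester = render_manchester(axiom, axset = axset),
    sentence = squish(sentence),
    flags = ctx$flags
  )
}

#' Verbalize every axiom of a loaded ontology
#'
#' Produces one record per supported axiom, in the axiom set's deterministic
#' order (axiom type, then Manchester rendering). Per-axiom template
#' failures never abort the run: such axioms get their Manchester rendering
#' as the sentence, flagged `generic_fallback`.
#'
#' @param axset An `owl_axiom_set` from [load_ontology()].
#' @param style `"explicit"` (default; restriction predicates read
#'   "is something that ...") or `"compact"`.
#' @param lexicon_csv Optional path to a user lexicon CSV overriding
#'   automatic lexicalization (see [read_lexicon_csv()]).
#' @return A tibble with columns `item_id`, `axiom_type`, `manchester`,
#'   `sentence` and `flags` (`;`-separated diagnostic flags, `""` when
#'   clean).
#' @export
#' @examples
#' path <- write_paper_examples(tempdir())["turtle"]
#' verbalize_all(load_ontology(path))
verbalize_all <- function(axset, style = c("explicit", "compact"),
                          lexicon_csv = NULL) {
  style <- match.arg(style)
  stopifnot(inherits(axset, "owl_axiom_set"))
  overrides <- if (!is.null(lexicon_csv)) read_lexicon_csv(lexicon_csv) else NULL
  lexicon <- build_lexicon(axset, overrides)
  recs <- lapply(axset$axioms, function(ax) {
    tryCatch(
      verbalize_axiom(ax, lexicon, style = style, axset = axset),
      error = function(e) {
        list(axiom_type = ax$type,
             manchester = render_manchester(ax, axset = axset),
             sentence = render_manchester(ax, axset = axset),
             flags = "generic_fallback")
      }
    )
  })
  tibble::tibble(
    item_id = sprintf("ax%04d", seq_along(recs)),
    axiom_type = vapply(recs, `[[`, "", "axiom_type"),
    manchester = vapply(recs, `[[`, "", "manchester"),
    sentence = vapply(recs, `[[`, "", "sentence"),
    flags = vapply(recs, function(r) paste(r$flags, collapse = ";"), "")
  )
}
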