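# Lexicalization: turning entity IRIs and rdfs:label values into word
# tokens usable in sentences, classifying property labels into verb-phrase
# shapes, and light English morphology (lemmatization, pluralization,
# third-person-singular inflection, article selection).

#' Lexicalize one entity
#'
#' Maps an entity to the word tokens a sentence will use. A present
#' `rdfs:label` is split on whitespace with letter case preserved (ontology
#' labels like "Saturday" keep their capitals). Without a label, tokens are
#' derived from the IRI's local fragment by splitting on underscores and
#' camelCase boundaries and lowercasing, digits kept — the fallback that
#' turns an unimported external term such as `...IAO_0000032` into
#' "iao 0000032" rather than silently inventing a name.
#'
#' @param iri Entity IRI.
#' @param label The entity's `rdfs:label`, or `NA` if it has none.
#' @param kind Entity kind (`"class"`, `"object_property"`, ...).
#' @return A `lex_entry`: list with `entity_iri`, `tokens`, `source`
#'   (`"label"` or `"iri_fragment"`), `phrase_kind` (`"noun_phrase"`, or
#'   `"verb_phrase"` for properties) and `flagged` (`TRUE` when even the
#'   IRI had no usable local fragment).
#' @export
#' @examples
#' lexicalize("http://purl.obolibrary.org/obo/IAO_0000032", NA)$tokens
#' lexicalize("http://example.org/people#HappyPerson", NA)$tokens
lexicalize <- function(iri, label = NA_character_, kind = "class") {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  flagged <- FALSE
  if (!is.na(label) && nzchar(label)) {
    tokens <- strsplit(squish(label), " ", fixed = TRUE)[[1L]]
    source <- "label"
  } else {
    frag <- iri_fragment(iri)
    if (!nzchar(frag)) {
      tokens <- iri
      source <- "iri_fragment"
      flagged <- TRUE
    } else {
      frag <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", frag)
      frag <- gsub("([A-Z]+)([A-Z][a-z])", "\\1_\\2", frag)
      tokens <- tolower(strsplit(frag, "[_[:space:]]+")[[1L]])
      tokens <- tokens[nzchar(tokens)]
      if (length(tokens) == 0L) { tokens <- iri; flagged <- TRUE }
      source <- "iri_fragment"
    }
  }
  structure(
    list(
      entity_iri = iri,
      tokens = tokens,
      source = source,
      phrase_kind = if (kind %in% c("object_property", "data_property")) {
        "verb_phrase"
      } else "noun_phrase",
      flagged = flagged
    ),
    class = "lex_entry"
  )
}

#' Classify a property label into a verb-phrase shape
#'
#' Biomedical ontology property labels follow naming conventions that this
#' prefix rule exploits: labels beginning "is"/"are" are copular ("is
#' about", "is realized in"), labels beginning "has"/"have" are possessive
#' ("has part", "has child"), and anything else is treated as a plain verb
#' with the first token as the verb head ("precedes").
#'
#' @param entry A `lex_entry` for an object or data property (or a character
#'   vector of tokens).
#' @return A list with `form` (`"copular"`, `"possessive"` or
#'   `"plain_verb"`) and `tokens`.
#' @export
#' @examples
#' classify_property(c("is", "about"))$form
#' classify_property(c("has", "child"))$form
#' classify_property("precedes")$form
classify_property <- function(entry) {
  tokens <- if (inherits(entry, "lex_entry")) entry$tokens else as.character(entry)
  stopifnot(length(tokens) >= 1L)
  head <- tolower(tokens[[1L]])
  form <- if (length(tokens) > 1L && head %in% c("is", "are")) {
    "copular"
  } else if (length(tokens) > 1L && head %in% c("has", "have")) {
    "possessive"
  } else {
    "plain_verb"
  }
  list(form = form, tokens = tokens)
}

# ---- morphology -------------------------------------------------------------

# irregular form -> lemma
LEMMA_EXCEPTIONS <- c(
  is = "be", are = "be", was = "be", were = "be", been = "be", am = "be",
  being = "be",
  has = "have", had = "have", having = "have",
  does = "do", did = "do",
  goes = "go", went = "go",
  children = "child", people = "person", men = "man", women = "woman",
  feet = "foot", teeth = "tooth", geese = "goose", mice = "mouse",
  lice = "louse", oxen = "ox", criteria = "criterion", phenomena = "phenomenon",
  bacteria = "bacterium", indices = "index", matrices = "matrix",
  vertices = "vertex", analyses = "analysis", hypotheses = "hypothesis",
  diagnoses = "diagnosis", theses = "thesis", crises = "crisis",
  lives = "life", knives = "knife", wives = "wife", leaves = "leaf",
  halves = "half", shelves = "shelf",
  # plural of sibilant-final nouns whose stem itself ends in a lone "s"
  buses = "bus", busses = "bus", gases = "gas", gasses = "gas",
  lenses = "lens", viruses = "virus", statuses = "status",
  corpuses = "corpus", atlases = "atlas", canvases = "canvas",
  biases = "bias", pancreases = "pancreas"
)

# words that are their own lemma even though they end like an inflection;
# includes the regression set for the stemming defect this package avoids
LEMMA_INVARIANT <- c(
  "data", "species", "series", "analysis", "status", "basis", "axis",
  "diagnosis", "hypothesis", "thesis", "crisis", "corpus", "virus",
  "news", "physics", "mathematics", "diabetes", "measles", "lens",
  "bias", "atlas", "canvas", "gas", "bus", "is", "this", "its", "as",
  "always", "perhaps", "was", "has", "yes", "molasses", "pancreas"
)

#' Lemmatize a word
#'
#' Dictionary-style lemmatization by exception table plus conservative
#' suffix rules — not suffix-stripping stemming, so a word that is already
#' a lemma returns itself: `lemmatize_token("data")` is `"data"`, never a
#' mutilated stem.
#'
#' @param token A single (alphabetic) word.
#' @return Its lemma.
#' @export
#' @examples
#' lemmatize_token("data")     # "data"
#' lemmatize_token("is")       # "be"
#' lemmatize_token("studies")  # "study"
lemmatize_token <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  low <- tolower(token)
  if (low %in% names(LEMMA_EXCEPTIONS)) return(unname(LEMMA_EXCEPTIONS[[low]]))
  if (low %in% LEMMA_INVARIANT) return(token)
  n <- nchar(low)
  if (n > 3L && endsWith(low, "ies")) {
    return(paste0(substr(token, 1L, n - 3L), "y"))
  }
  if (n > 2L && endsWith(low, "es")) {
    stem <- substr(token, 1L, n - 2L)
    low_stem <- tolower(stem)
    if (endsWith(low_stem, "ss") || endsWith(low_stem, "x") ||
        endsWith(low_stem, "zz") || endsWith(low_stem, "ch") ||
        endsWith(low_stem, "sh")) {
      return(stem)
    }
    return(substr(token, 1L, n - 1L))
  }
  if (n > 2L && endsWith(low, "s") && !endsWith(low, "ss") && !endsWith(low, "us") &&
      !endsWith(low, "is")) {
    return(substr(token, 1L, n - 1L))
  }
  token
}

#' Pluralize a regular noun
#'
#' Regular English pluralization (y -> ies after a consonant; es after a
#' sibilant; s otherwise). Inverse of [lemmatize_token()] on regular nouns.
#'
#' @param token A singular noun.
#' @return Its plural form.
#' @export
#' @examples
#' pluralize_noun("study")
#' pluralize_noun("box")
pluralize_noun <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  low <- tolower(token)
  n <- nchar(token)
  if (endsWith(low, "y") && n > 1L &&
      !substr(low, n - 1L, n - 1L) %in% c("a", "e", "i", "o", "u")) {
    return(paste0(substr(token, 1L, n - 1L), "ies"))
  }
  if (endsWith(low, "s") || endsWith(low, "x") || endsWith(low, "z") ||
      endsWith(low, "ch") || endsWith(low, "sh")) {
    return(paste0(token, "es"))
  }
  paste0(token, "s")
}

VERB_3SG_EXCEPTIONS <- c(be = "is", have = "has", do = "does", go = "goes")

#' Third-person-singular form of a verb lemma
#'
#' @param lemma A verb lemma.
#' @return The 3rd-person-singular present form ("precede" -> "precedes").
#' @export
verb_3sg <- function(lemma) {
  stopifnot(is.character(lemma), length(lemma) == 1L)
  low <- tolower(lemma)
  if (low %in% names(VERB_3SG_EXCEPTIONS)) return(unname(VERB_3SG_EXCEPTIONS[[low]]))
  n <- nchar(lemma)
  if (endsWith(low, "y") && n > 1L &&
      !substr(low, n - 1L, n - 1L) %in% c("a", "e", "i", "o", "u")) {
    return(paste0(substr(lemma, 1L, n - 1L), "ies"))
  }
  if (endsWith(low, "s") || endsWith(low, "x") || endsWith(low, "z") ||
      endsWith(low, "ch") || endsWith(low, "sh") || endsWith(low, "o")) {
    return(paste0(lemma, "es"))
  }
  paste0(lemma, "s")
}

# consonant-initial words taking "an" (silent h and similar)
AN_EXCEPTIONS <- c("hour", "hourly", "honest", "honestly", "honor", "honour",
                   "honorary", "heir", "heirloom", "herb", "herbal")
# vowel-initial words taking "a" (consonant pronunciation)
A_EXCEPTIONS_RE <- "^(uni[a-z]|use|usa|usu|uti|ubi|eu|one$|once$|ewe)"

#' Choose the indefinite article for a noun-phrase head
#'
#' Vowel-letter heuristic with a pronunciation exception list: "a human
#' subject" but "an iao 0000032" and "an hour".
#'
#' @param head First word of the noun phrase.
#' @return `"a"` or `"an"`.
#' @export
#' @examples
#' realize_article("iao")   # "an"
#' realize_article("human") # "a"
#' realize_article("hour")  # "an"
realize_article <- function(head) {
  stopifnot(is.character(head), length(head) == 1L, nzchar(head))
  low <- tolower(head)
  if (low %in% AN_EXCEPTIONS) return("an")
  if (grepl(A_EXCEPTIONS_RE, low)) return("a")
  if (substr(low, 1L, 1L) %in% c("a", "e", "i", "o", "u")) "an" else "a"
}

#' Read a user lexicon CSV
#'
#' An optional override table for automatic lexicalization, one row per
#' entity: columns `iri`, `surface` (space-separated tokens) and
#' `phrase_kind` (`noun_phrase` or `verb_phrase`).
#'
#' @param path CSV path.
#' @return A tibble with those three columns.
#' @export
read_lexicon_csv <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("iri", "surface", "phrase_kind")
  if (!all(required %in% names(tb))) {
    stop("lexicon CSV must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tb[required]
}

# Build the IRI -> lex_entry context for a loaded ontology, with optional
# user-lexicon overrides.
build_lexicon <- function(axset, overrides = NULL) {
  ents <- axset$entities
  entries <- lapply(seq_len(nrow(ents)), function(i) {
    lexicalize(ents$iri[i], ents$label[i], ents$kind[i])
  })
  names(entries) <- ents$iri
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      iri <- overrides$iri[i]
      entries[[iri]] <- structure(
        list(
          entity_iri = iri,
          tokens = strsplit(squish(overrides$surface[i]), " ", fixed = TRUE)[[1L]],
          source = "label",
          phrase_kind = overrides$phrase_kind[i],
          flagged = FALSE
        ),
        class = "lex_entry"
      )
    }
  }
  entries
}

# lexicon lookup with on-the-fly fallback for IRIs outside the entity index
lex_get <- function(lexicon, iri, kind = "class") {
  lexicon[[iri]] %||% lexicalize(iri, NA_character_, kind)
}
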