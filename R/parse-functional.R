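# OWL 2 functional-syntax reader: tokenizer plus a recursive-descent parse
# into the shared form tree.

tokenize_functional <- function(text) {
  pats <- c(
    iriref = "^<[^<>\"\\s]*>",
    string = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    dcaret = "^\\^\\^",
    langtag = "^@[A-Za-z]+(?:-[A-Za-z0-9]+)*",
    pname  = "^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?",
    pname_ns = "^[A-Za-z][A-Za-z0-9_.-]*:",
    name   = "^[A-Za-z][A-Za-z0-9_-]*",
    number = "^[+-]?[0-9]+(?:\\.[0-9]+)?",
    punct  = "^[()=]"
  )
  tokens <- character(); types <- character()
  pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[\\s]+", rest, perl = TRUE))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    if (substr(rest, 1, 1) == "#") {
      nl <- regexpr("\n", rest, fixed = TRUE)
      if (nl == -1L) break
      pos <- pos + nl; next
    }
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m)) {
        tokens <- c(tokens, m); types <- c(types, ty)
        pos <- pos + nchar(m); hit <- TRUE
        break
      }
    }
    if (!hit) stop("functional-syntax tokenizer: unexpected input at: ",
                   substr(rest, 1, 30), call. = FALSE)
  }
  list(tokens = tokens, types = types)
}

parse_functional <- function(text) {
  tk <- tokenize_functional(text)
  toks <- tk$tokens; types <- tk$types
  i <- 1L
  prefixes <- BASE_PREFIXES

  peek <- function() if (i <= length(toks)) toks[[i]] else NA_character_
  peek_type <- function() if (i <= length(toks)) types[[i]] else NA_character_
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect <- function(tok) {
    if (!identical(peek(), tok)) {
      stop("functional-syntax parser: expected '", tok, "', got '", peek(), "'",
           call. = FALSE)
    }
    advance()
  }
  expand_pname <- function(pn) {
    colon <- regexpr(":", pn, fixed = TRUE)
    pfx <- substr(pn, 1L, colon - 1L)
    if (!pfx %in% names(prefixes)) {
      stop("functional-syntax parser: undeclared prefix '", pfx, ":'", call. = FALSE)
    }
    paste0(prefixes[[pfx]], substr(pn, colon + 1L, nchar(pn)))
  }

  # one term: NAME(...) | IRI | pname | literal
  parse_term <- function() {
    ty <- peek_type(); tok <- peek()
    if (ty == "iriref") { advance(); return(list(op = "IRI", iri = substr(tok, 2, nchar(tok) - 1L))) }
    if (ty == "pname") { advance(); return(list(op = "IRI", iri = expand_pname(tok))) }
    if (ty == "number") { advance(); return(owl_literal(tok, xsd_iri("integer"))) }
    if (ty == "string") {
      advance()
      val <- unescape_turtle_string(tok)
      if (identical(peek_type(), "dcaret")) {
        advance()
        dtok <- advance()
        dt <- if (startsWith(dtok, "<")) substr(dtok, 2, nchar(dtok) - 1L) else expand_pname(dtok)
        return(owl_literal(val, dt))
      }
      if (identical(peek_type(), "langtag")) advance()
      return(owl_literal(val, xsd_iri("string")))
    }
    if (ty == "name") {
      advance()
      if (!identical(peek(), "(")) return(list(op = "IRI", iri = tok))
      advance()
      args <- list()
      while (!identical(peek(), ")")) {
        if (is.na(peek())) stop("functional-syntax parser: unbalanced '('", call. = FALSE)
        args[[length(args) + 1L]] <- parse_term()
      }
      advance()
      return(list(op = tok, args = args))
    }
    stop("functional-syntax parser: unexpected token '", tok, "'", call. = FALSE)
  }

  forms <- list()
  while (!is.na(peek())) {
    if (identical(peek(), "Prefix")) {
      advance(); expect("(")
      pn <- advance()          # 'pfx:' (or ':' for the default prefix)
      expect("=")
      iri <- advance()
      expect(")")
      prefixes[[sub(":$", "", pn)]] <- substr(iri, 2, nchar(iri) - 1L)
      next
    }
    if (identical(peek(), "Ontology")) {
      advance(); expect("(")
      # optional ontology IRI and version IRI
      while (peek_type() %in% c("iriref")) advance()
      while (!identical(peek(), ")")) {
        if (is.na(peek())) stop("functional-syntax parser: unbalanced Ontology(", call. = FALSE)
        forms[[length(forms) + 1L]] <- parse_term()
      }
      advance()
      next
    }
    forms[[length(forms) + 1L]] <- parse_term()
  }

  model <- forms_to_model(forms)
  model$prefixes <- prefixes[!names(prefixes) %in% names(BASE_PREFIXES)]
  model
}
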