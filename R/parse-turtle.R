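# A small Turtle reader producing the triple table consumed by
# triples_to_model(). Covers the Turtle constructs OWL serializations use:
# prefix directives, prefixed names and full IRIs, 'a', predicate-object and
# object lists, anonymous nodes [...], collections (...), and typed /
# language-tagged literals. Not a general-purpose Turtle implementation.

tokenize_turtle <- function(text) {
  pats <- c(
    iriref  = "^<[^<>\"{}|^`\\\\[:cntrl:]]*>",
    string  = "^\"(?:[^\"\\\\]|\\\\.)*\"",
    dcaret  = "^\\^\\^",
    prefix_kw = "^@prefix|^@base|^PREFIX|^BASE",
    langtag = "^@[A-Za-z]+(?:-[A-Za-z0-9]+)*",
    number  = "^[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",
    pname   = "^(?:[A-Za-z][A-Za-z0-9_.-]*)?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?",
    pname_ns = "^(?:[A-Za-z][A-Za-z0-9_.-]*)?:",
    name    = "^[A-Za-z][A-Za-z0-9_-]*",
    punct   = "^[][();,.]"
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
    if (!hit) {
      stop("Turtle tokenizer: unexpected input at: ",
           substr(rest, 1, 30), call. = FALSE)
    }
  }
  list(tokens = tokens, types = types)
}

unescape_turtle_string <- function(s) {
  s <- substr(s, 2L, nchar(s) - 1L)
  s <- gsub("\\\\n", "\n", s)
  s <- gsub("\\\\t", "\t", s)
  s <- gsub("\\\\\"", "\"", s)
  gsub("\\\\\\\\", "\\\\", s)
}

parse_turtle <- function(text) {
  tk <- tokenize_turtle(text)
  toks <- tk$tokens; types <- tk$types
  i <- 1L
  prefixes <- BASE_PREFIXES
  bn <- 0L
  rows <- list()
  emit <- function(s, p, o, o_kind, dtype = NA_character_, lang = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, o_kind = o_kind,
                                       dtype = dtype, lang = lang)
  }
  fresh_bnode <- function() { bn <<- bn + 1L; paste0("_:tb", bn) }
  peek <- function() if (i <= length(toks)) toks[[i]] else NA_character_
  peek_type <- function() if (i <= length(toks)) types[[i]] else NA_character_
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect <- function(tok) {
    if (!identical(peek(), tok)) stop("Turtle parser: expected '", tok, "' near token ",
                                      i, " ('", peek(), "')", call. = FALSE)
    advance()
  }
  expand_pname <- function(pn) {
    colon <- regexpr(":", pn, fixed = TRUE)
    pfx <- substr(pn, 1L, colon - 1L)
    local <- substr(pn, colon + 1L, nchar(pn))
    if (!pfx %in% names(prefixes)) stop("Turtle parser: undeclared prefix '", pfx, ":'",
                                        call. = FALSE)
    paste0(prefixes[[pfx]], local)
  }

  # term in object position: returns list(value, kind, dtype, lang)
  parse_object <- function() {
    ty <- peek_type(); tok <- peek()
    if (ty == "iriref") { advance(); return(list(v = substr(tok, 2, nchar(tok) - 1L), k = "iri")) }
    if (ty %in% c("pname", "pname_ns")) { advance(); return(list(v = expand_pname(tok), k = "iri")) }
    if (ty == "name" && tok %in% c("true", "false")) {
      advance(); return(list(v = tok, k = "literal", dtype = xsd_iri("boolean")))
    }
    if (ty == "name" && tok == "a") stop("Turtle parser: 'a' in object position", call. = FALSE)
    if (ty == "number") {
      advance()
      dt <- if (grepl("[.eE]", tok)) xsd_iri("decimal") else xsd_iri("integer")
      return(list(v = tok, k = "literal", dtype = dt))
    }
    if (ty == "string") {
      advance()
      val <- unescape_turtle_string(tok)
      if (identical(peek_type(), "dcaret")) {
        advance()
        dty <- peek_type(); dtok <- advance()
        dt <- if (dty == "iriref") substr(dtok, 2, nchar(dtok) - 1L) else expand_pname(dtok)
        return(list(v = val, k = "literal", dtype = dt))
      }
      if (identical(peek_type(), "langtag")) {
        lt <- advance()
        return(list(v = val, k = "literal", dtype = xsd_iri("string"),
                    lang = sub("^@", "", lt)))
      }
      return(list(v = val, k = "literal", dtype = xsd_iri("string")))
    }
    if (tok == "[") {
      advance()
      node <- fresh_bnode()
      if (!identical(peek(), "]")) parse_predicate_object_list(node)
      expect("]")
      return(list(v = node, k = "bnode"))
    }
    if (tok == "(") {
      advance()
      items <- list()
      while (!identical(peek(), ")")) items[[length(items) + 1L]] <- parse_object()
      expect(")")
      if (length(items) == 0L) return(list(v = rdf_iri("nil"), k = "iri"))
      nodes <- vapply(items, function(x) fresh_bnode(), "")
      for (j in seq_along(items)) {
        it <- items[[j]]
        emit(nodes[[j]], rdf_iri("first"), it$v, it$k,
             it$dtype %||% NA_character_, it$lang %||% NA_character_)
        nxt <- if (j < length(items)) nodes[[j + 1L]] else rdf_iri("nil")
        emit(nodes[[j]], rdf_iri("rest"), nxt, "iri")
      }
      return(list(v = nodes[[1L]], k = "bnode"))
    }
    stop("Turtle parser: unexpected token '", tok, "' in object position", call. = FALSE)
  }

  parse_predicate <- function() {
    ty <- peek_type(); tok <- peek()
    if (ty == "name" && tok == "a") { advance(); return(rdf_iri("type")) }
    if (ty == "iriref") { advance(); return(substr(tok, 2, nchar(tok) - 1L)) }
    if (ty %in% c("pname", "pname_ns")) { advance(); return(expand_pname(tok)) }
    stop("Turtle parser: unexpected token '", tok, "' in predicate position", call. = FALSE)
  }

  parse_predicate_object_list <- function(subj) {
    repeat {
      p <- parse_predicate()
      repeat {
        o <- parse_object()
        emit(subj, p, o$v, o$k, o$dtype %||% NA_character_, o$lang %||% NA_character_)
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # a trailing ';' before '.' or ']' is legal
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else break
    }
  }

  while (i <= length(toks)) {
    if (peek_type() == "prefix_kw") {
      kw <- advance()
      if (kw %in% c("@prefix", "PREFIX")) {
        pn <- advance()   # 'pfx:'
        pfx <- sub(":$", "", pn)
        iri <- advance()
        prefixes[[pfx]] <- substr(iri, 2, nchar(iri) - 1L)
      } else {
        advance()         # @base <iri>: accepted, unused
      }
      if (identical(peek(), ".")) advance()
      next
    }
    subj <- {
      ty <- peek_type(); tok <- peek()
      if (ty == "iriref") { advance(); substr(tok, 2, nchar(tok) - 1L) }
      else if (ty %in% c("pname", "pname_ns")) { advance(); expand_pname(tok) }
      else if (identical(tok, "[")) {
        advance(); node <- fresh_bnode()
        if (!identical(peek(), "]")) parse_predicate_object_list(node)
        expect("]")
        node
      } else stop("Turtle parser: unexpected token '", tok, "' in subject position",
                  call. = FALSE)
    }
    if (!identical(peek(), ".")) parse_predicate_object_list(subj)
    expect(".")
  }

  tr <- if (length(rows)) {
    tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
      data.frame(s = r$s, p = r$p, o = r$o, o_kind = r$o_kind,
                 dtype = r$dtype, lang = r$lang, stringsAsFactors = FALSE)
    })))
  } else new_triples()
  list(triples = tr, prefixes = prefixes)
}
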