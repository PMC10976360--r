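# Parser and serializer for the SPARQL SELECT fragment used throughout the
# package: basic graph patterns (variables allowed in any position),
# predicate-object lists with ';', VALUES blocks in single-variable
# parenthesized form, FILTER with numeric comparisons chained by && / ||,
# and OPTIONAL groups.  The abstract syntax tree (AST) is a plain list so
# post-correction passes can rewrite it and re-serialize canonically.

# ---- terms -----------------------------------------------------------------

new_term <- function(kind, text, lex = NULL, datatype = NA_character_) {
  structure(list(kind = kind, text = text, lex = lex, datatype = datatype),
            class = "sparql_term")
}

term_var <- function(name) new_term("var", paste0("?", sub("^\\?", "", name)))
term_pname <- function(text) new_term("pname", text)
term_iri <- function(iri) new_term("iri", paste0("<", gsub("^<|>$", "", iri), ">"))
term_literal <- function(lex, datatype = NA_character_) {
  text <- paste0('"', escape_literal(lex), '"',
                 if (!is.na(datatype)) paste0("^^", datatype) else "")
  new_term("literal", text, lex = lex, datatype = datatype)
}
term_number <- function(x) {
  new_term("number", if (is.character(x)) x else format_quantity(x))
}

token_to_term <- function(tok) {
  switch(tok$type,
    string = {
      p <- parse_string_token(tok$text)
      term_literal(p$lex, p$datatype)
    },
    iri = new_term("iri", tok$text),
    var = new_term("var", tok$text),
    pname = new_term("pname", tok$text),
    number = new_term("number", tok$text),
    name = new_term("name", tok$text),
    stop_syntax(sprintf("unexpected token %s", dQuote(tok$text)))
  )
}

var_name <- function(term) sub("^\\?", "", term$text)

is_var <- function(term) identical(term$kind, "var")

# ---- parser ----------------------------------------------------------------

# Returns list(type = "select", distinct, vars (character, '?'-prefixed),
# prefixes (named character), where = list of items). Items are lists with a
# `type` of "triple" (s/p/o terms), "values" (var, literals = list of terms),
# "filter" (comps = list(lhs, op, rhs), conns = character), or
# "optional" (items).
parse_sparql <- function(query) {
  toks <- tokenize_rdf(query, what = "SPARQL query")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L

  prefixes <- character()
  while (peek_is(st, "name", "PREFIX")) {
    advance(st)
    pn <- expect_type(st, "pname", "prefix name")
    iri <- expect_type(st, "iri", "prefix IRI")
    prefixes[sub(":.*$", "", pn$text)] <- gsub("^<|>$", "", iri$text)
  }

  expect_kw(st, "SELECT")
  distinct <- FALSE
  if (peek_is(st, "name", "DISTINCT")) {
    distinct <- TRUE
    advance(st)
  }
  vars <- character()
  while (peek_type(st) == "var") vars <- c(vars, advance(st)$text)
  if (!length(vars)) stop_syntax("SELECT clause names no variables")

  expect_kw(st, "WHERE")
  expect_punct(st, "{")
  items <- parse_group(st)
  expect_punct(st, "}")
  if (st$i <= nrow(st$toks)) {
    stop_syntax(sprintf("trailing content after query: %s",
                        dQuote(st$toks$text[st$i])))
  }
  structure(list(type = "select", distinct = distinct, vars = vars,
                 prefixes = prefixes, where = items),
            class = "sparql_query")
}

parse_group <- function(st) {
  items <- list()
  repeat {
    if (peek_type(st) == "eof") stop_syntax("unbalanced braces: missing '}'")
    if (peek_is(st, "punct", "}")) return(items)
    if (peek_is(st, "name", "VALUES")) {
      items[[length(items) + 1L]] <- parse_values(st)
    } else if (peek_is(st, "name", "FILTER")) {
      items[[length(items) + 1L]] <- parse_filter(st)
    } else if (peek_is(st, "name", "OPTIONAL")) {
      advance(st)
      expect_punct(st, "{")
      inner <- parse_group(st)
      expect_punct(st, "}")
      items[[length(items) + 1L]] <- list(type = "optional", items = inner)
    } else {
      items <- c(items, parse_triples(st))
    }
  }
}

parse_values <- function(st) {
  advance(st) # VALUES
  expect_punct(st, "(")
  v <- expect_type(st, "var", "VALUES variable")
  expect_punct(st, ")")
  expect_punct(st, "{")
  lits <- list()
  while (peek_is(st, "punct", "(")) {
    advance(st)
    tok <- advance(st)
    if (!tok$type %in% c("string", "number")) {
      stop_syntax("VALUES rows must contain literals")
    }
    lits[[length(lits) + 1L]] <- token_to_term(tok)
    expect_punct(st, ")")
  }
  expect_punct(st, "}")
  list(type = "values", var = v$text, literals = lits)
}

parse_filter <- function(st) {
  advance(st) # FILTER
  expect_punct(st, "(")
  comps <- list()
  conns <- character()
  repeat {
    comps[[length(comps) + 1L]] <- parse_comparison(st)
    if (peek_type(st) == "op" && st$toks$text[st$i] %in% c("&&", "||")) {
      conns <- c(conns, advance(st)$text)
    } else break
  }
  expect_punct(st, ")")
  list(type = "filter", comps = comps, conns = conns)
}

parse_comparison <- function(st) {
  lhs <- advance(st)
  if (!lhs$type %in% c("var", "number")) {
    stop_syntax(sprintf("unexpected %s in FILTER", dQuote(lhs$text)))
  }
  op <- advance(st)
  if (op$type != "op" || !op$text %in% c(">", "<", ">=", "<=", "=", "!=")) {
    stop_syntax(sprintf("expected comparison operator, got %s", dQuote(op$text)))
  }
  rhs <- advance(st)
  if (!rhs$type %in% c("var", "number")) {
    stop_syntax(sprintf("unexpected %s in FILTER", dQuote(rhs$text)))
  }
  list(lhs = token_to_term(lhs), op = op$text, rhs = token_to_term(rhs))
}

parse_triples <- function(st) {
  subj_tok <- advance(st)
  if (!subj_tok$type %in% c("var", "pname", "iri")) {
    stop_syntax(sprintf("invalid triple subject %s", dQuote(subj_tok$text)))
  }
  subj <- token_to_term(subj_tok)
  out <- list()
  repeat {
    pred_tok <- advance(st)
    if (pred_tok$type == "name" && pred_tok$text == "a") {
      pred <- term_pname("rdf:type")
    } else if (pred_tok$type %in% c("var", "pname", "iri")) {
      pred <- token_to_term(pred_tok)
    } else {
      stop_syntax(sprintf("invalid predicate %s", dQuote(pred_tok$text)))
    }
    obj_tok <- advance(st)
    if (!obj_tok$type %in% c("var", "pname", "iri", "string", "number")) {
      stop_syntax(sprintf("invalid triple object %s", dQuote(obj_tok$text)))
    }
    obj <- token_to_term(obj_tok)
    out[[length(out) + 1L]] <- list(type = "triple", s = subj, p = pred, o = obj)
    if (peek_is(st, "punct", ";")) {
      advance(st)
      next
    }
    if (peek_is(st, "punct", ".")) advance(st)
    return(out)
  }
}

peek_type <- function(st) {
  if (st$i > nrow(st$toks)) "eof" else st$toks$type[st$i]
}

peek_is <- function(st, type, text) {
  st$i <= nrow(st$toks) && st$toks$type[st$i] == type &&
    (type != "name" && st$toks$text[st$i] == text ||
     type == "name" && toupper(st$toks$text[st$i]) == toupper(text))
}

advance <- function(st) {
  if (st$i > nrow(st$toks)) stop_syntax("unexpected end of query")
  tok <- st$toks[st$i, ]
  st$i <- st$i + 1L
  list(text = tok$text, type = tok$type)
}

expect_type <- function(st, type, what) {
  tok <- advance(st)
  if (tok$type != type) {
    stop_syntax(sprintf("expected %s, got %s", what, dQuote(tok$text)))
  }
  tok
}

expect_kw <- function(st, kw) {
  tok <- advance(st)
  if (tok$type != "name" || toupper(tok$text) != kw) {
    stop_syntax(sprintf("expected %s, got %s", kw, dQuote(tok$text)))
  }
}

expect_punct <- function(st, ch) {
  tok <- advance(st)
  if (tok$text != ch) {
    stop_syntax(sprintf("expected '%s', got %s", ch, dQuote(tok$text)))
  }
}

# ---- serializer ------------------------------------------------------------

serialize_term <- function(term) term$text

serialize_item <- function(item) {
  switch(item$type,
    triple = paste(serialize_term(item$s), serialize_term(item$p),
                   serialize_term(item$o), "."),
    values = paste0("VALUES (", item$var, ") { ",
                    paste(vapply(item$literals, function(l)
                      paste0("(", serialize_term(l), ")"), character(1)),
                      collapse = " "),
                    " }"),
    filter = paste0("FILTER ( ", serialize_filter_expr(item), " )"),
    optional = paste(c("OPTIONAL {",
                       vapply(item$items, serialize_item, character(1)),
                       "}"), collapse = "\n"),
    stop("unknown item type: ", item$type)
  )
}

serialize_filter_expr <- function(item) {
  parts <- vapply(item$comps, function(cmp)
    paste(serialize_term(cmp$lhs), cmp$op, serialize_term(cmp$rhs)), character(1))
  out <- parts[1]
  for (k in seq_along(item$conns)) {
    out <- paste(out, item$conns[k], parts[k + 1L])
  }
  out
}

serialize_sparql <- function(ast) {
  stopifnot(inherits(ast, "sparql_query"))
  head <- paste0("SELECT ", if (ast$distinct) "DISTINCT " else "",
                 paste(ast$vars, collapse = " "))
  body <- vapply(ast$where, serialize_item, character(1))
  paste(c(head, "WHERE {", body, "}"), collapse = "\n")
}

# All triple items of a query, descending into OPTIONAL groups.
ast_triples <- function(ast) {
  collect <- function(items) {
    out <- list()
    for (it in items) {
      if (it$type == "triple") out[[length(out) + 1L]] <- it
      if (it$type == "optional") out <- c(out, collect(it$items))
    }
    out
  }
  collect(ast$where)
}

ast_filters <- function(ast) {
  Filter(function(it) it$type == "filter", ast$where)
}

# Numbers in filters and literals: full precision, trailing zeros trimmed.
format_quantity <- function(x) {
  format(signif(x, 12), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}
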