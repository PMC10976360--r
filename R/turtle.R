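# Minimal Turtle / N-Triples reader covering the subset this package emits
# and consumes: @prefix declarations, prefixed names, full IRIs, plain and
# ^^-typed literals, bare numbers, 'a' for rdf:type, and ';'
# predicate-object lists.  Terms are normalized to full IRIs internally.

default_prefixes <- function() {
  c(os   = "http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#",
    rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl  = "http://www.w3.org/2002/07/owl#",
    xsd  = "http://www.w3.org/2001/XMLSchema#",
    skos = "http://www.w3.org/2004/02/skos/core#")
}

#' @noRd
expand_pname <- function(text, prefixes) {
  pre <- sub(":.*$", "", text)
  local <- sub("^[^:]*:", "", text)
  if (!pre %in% names(prefixes)) {
    stop_syntax(sprintf("undeclared prefix %s", dQuote(paste0(pre, ":"))))
  }
  paste0(prefixes[[pre]], local)
}

term_to_node <- function(term, prefixes) {
  # returns list(key, kind, lex, dt) with full-IRI keys
  switch(term$kind,
    iri = {
      iri <- gsub("^<|>$", "", term$text)
      list(key = iri, kind = "iri", lex = NA_character_, dt = NA_character_)
    },
    pname = {
      iri <- expand_pname(term$text, prefixes)
      list(key = iri, kind = "iri", lex = NA_character_, dt = NA_character_)
    },
    literal = {
      dt <- term$datatype
      if (!is.na(dt) && !startsWith(dt, "<")) {
        dt <- expand_pname(dt, prefixes)
      } else if (!is.na(dt)) {
        dt <- gsub("^<|>$", "", dt)
      }
      key <- paste0('"', term$lex, '"', if (!is.na(dt)) paste0("^^", dt) else "")
      list(key = key, kind = "literal", lex = term$lex, dt = dt)
    },
    number = {
      dt <- paste0(default_prefixes()[["xsd"]],
                   if (grepl("[.eE]", term$text)) "decimal" else "integer")
      list(key = paste0('"', term$text, '"^^', dt), kind = "literal",
           lex = term$text, dt = dt)
    },
    stop_syntax(sprintf("term %s not allowed here", dQuote(term$text)))
  )
}

# Parse Turtle text (or a file path) into a triple table.
parse_turtle <- function(x) {
  if (length(x) == 1L && !grepl("[\n{@\"]", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  x <- paste(x, collapse = "\n")
  toks <- tokenize_rdf(x, what = "Turtle document")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  prefixes <- default_prefixes()

  s <- p <- okey <- okind <- olex <- odt <- character()
  add <- function(su, pr, ob) {
    s[[length(s) + 1L]] <<- su$key
    p[[length(p) + 1L]] <<- pr$key
    okey[[length(okey) + 1L]] <<- ob$key
    okind[[length(okind) + 1L]] <<- ob$kind
    olex[[length(olex) + 1L]] <<- ob$lex
    odt[[length(odt) + 1L]] <<- ob$dt
  }

  while (st$i <= nrow(st$toks)) {
    if (peek_is(st, "name", "@prefix") || st$toks$text[st$i] == "@prefix") {
      advance(st)
      pn <- expect_type(st, "pname", "prefix name")
      iri <- expect_type(st, "iri", "prefix IRI")
      expect_punct(st, ".")
      prefixes[sub(":.*$", "", pn$text)] <- gsub("^<|>$", "", iri$text)
      next
    }
    subj_tok <- advance(st)
    if (!subj_tok$type %in% c("pname", "iri")) {
      stop_syntax(sprintf("invalid Turtle subject %s", dQuote(subj_tok$text)))
    }
    subj <- term_to_node(token_to_term(subj_tok), prefixes)
    repeat {
      pred_tok <- advance(st)
      if (pred_tok$type == "name" && pred_tok$text == "a") {
        pred <- term_to_node(term_pname("rdf:type"), prefixes)
      } else if (pred_tok$type %in% c("pname", "iri")) {
        pred <- term_to_node(token_to_term(pred_tok), prefixes)
      } else {
        stop_syntax(sprintf("invalid Turtle predicate %s", dQuote(pred_tok$text)))
      }
      repeat {
        obj_tok <- advance(st)
        if (!obj_tok$type %in% c("pname", "iri", "string", "number")) {
          stop_syntax(sprintf("invalid Turtle object %s", dQuote(obj_tok$text)))
        }
        add(subj, pred, term_to_node(token_to_term(obj_tok), prefixes))
        if (peek_is(st, "punct", ",")) advance(st) else break
      }
      if (peek_is(st, "punct", ";")) advance(st) else break
    }
    expect_punct(st, ".")
  }

  structure(list(
    triples = data.frame(s = s, p = p, o = okey, o_kind = okind,
                         o_lex = olex, o_dt = odt, stringsAsFactors = FALSE),
    prefixes = prefixes), class = "triple_table")
}

# objects of (s, p, *) in a triple table
tt_objects <- function(tt, s, p) {
  sel <- tt$triples$s == s & tt$triples$p == p
  tt$triples[sel, , drop = FALSE]
}

# subjects of (*, p, o)
tt_subjects <- function(tt, p, o) {
  sel <- tt$triples$p == p & tt$triples$o == o
  unique(tt$triples$s[sel])
}
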