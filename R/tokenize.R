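# Shared lexer for the Turtle reader and the SPARQL parser.
#
# Token types:
#   string  quoted literal, optionally ^^-typed ("373"^^xsd:decimal)
#   iri     <http://...>
#   var     ?name
#   pname   prefixed name (os:hasBoilingPoint), possibly with empty local part
#   name    bare identifier / keyword (SELECT, WHERE, a, ...)
#   number  numeric literal
#   op      comparison / boolean operator
#   punct   structural punctuation

.token_regex <- paste0(
  '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^(?:<[^<>"{}|^`\\s]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*))?',
  '|<[^<>"{}|^`\\s]*>',
  '|\\?[A-Za-z_][A-Za-z0-9_]*',
  '|@prefix',
  '|[A-Za-z][A-Za-z0-9_.-]*:(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?',
  '|[A-Za-z_][A-Za-z0-9_]*',
  '|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?',
  '|&&|\\|\\||>=|<=|!=|[=<>]',
  '|[{}().;,\\[\\]]'
)

# Tokenize `x`; any non-whitespace character outside a token is a syntax error.
tokenize_rdf <- function(x, what = "input") {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr(.token_regex, x, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    if (grepl("[^[:space:]]", x)) {
      stop_syntax(sprintf("cannot tokenize %s near %s", what,
                          substr(trimws(x), 1, 30)))
    }
    return(data.frame(text = character(), type = character()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # verify the gaps between tokens are pure whitespace
  covered <- rep(FALSE, nchar(x))
  for (i in seq_along(starts)) covered[seq(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(x, "")[[1]]
  bad <- which(!covered & !grepl("[[:space:]]", chars))
  if (length(bad)) {
    stop_syntax(sprintf("unexpected character %s in %s near position %d",
                        dQuote(chars[bad[1]]), what, bad[1]))
  }
  text <- substring(x, starts, starts + lens - 1L)
  type <- classify_tokens(text)
  data.frame(text = text, type = type, stringsAsFactors = FALSE)
}

classify_tokens <- function(text) {
  type <- rep(NA_character_, length(text))
  first <- substr(text, 1, 1)
  type[first == '"'] <- "string"
  type[first == "<" & nchar(text) > 1 & endsWith(text, ">")] <- "iri"
  type[first == "?" & nchar(text) > 1] <- "var"
  type[is.na(type) & text == "@prefix"] <- "name"
  type[is.na(type) & grepl("^[A-Za-z][A-Za-z0-9_.-]*:", text)] <- "pname"
  type[is.na(type) & grepl("^[A-Za-z_][A-Za-z0-9_]*$", text)] <- "name"
  type[is.na(type) & grepl("^[+-]?[0-9]", text)] <- "number"
  type[is.na(type) & text %in% c("&&", "||", ">=", "<=", "!=", "=", "<", ">")] <- "op"
  type[is.na(type)] <- "punct"
  type
}

# Split a string token into lexical form and datatype IRI/pname (NA if plain).
parse_string_token <- function(tok) {
  m <- regexpr('^"(?:[^"\\\\]|\\\\.)*"', tok, perl = TRUE)
  quoted <- regmatches(tok, m)
  lex <- unescape_literal(substr(quoted, 2, nchar(quoted) - 1L))
  rest <- substr(tok, attr(m, "match.length") + 1L, nchar(tok))
  dt <- if (nzchar(rest)) sub("^\\^\\^", "", rest) else NA_character_
  list(lex = lex, datatype = dt)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

stop_syntax <- function(msg) {
  stop(structure(class = c("chemkgqa_syntax_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
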