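# Sequence-to-sequence-safe encoding of SPARQL queries.
#
# Text-to-text language-model tokenizers trained on natural language treat
# '<', '>', '{' and '}' as out-of-vocabulary and strip whitespace before a
# question mark, which makes the '?' variable marker ambiguous.  Queries are
# therefore encoded before training/inference: structural characters become
# HTML entities and the variable prefix '?' becomes 'var_'.

CHAR_MAP <- c("<" = "&lt;", ">" = "&gt;", "{" = "&lcub;", "}" = "&rcub;")
RESERVED_SEQS <- c("var_", unname(CHAR_MAP))

#' Encode a SPARQL query for a seq2seq model
#'
#' Replaces every variable token `?name` occurring outside quoted literals
#' with `var_name`, and every `<`, `>`, `{`, `}` (globally, including inside
#' literals) with its HTML entity.  Whitespace is preserved byte-for-byte,
#' so `decode_sparql()` is an exact inverse.
#'
#' @param query SPARQL query text.  Must not contain any of the reserved
#'   sequences `var_`, `&lt;`, `&gt;`, `&lcub;`, `&rcub;`.
#' @return The encoded query string.
#' @seealso [decode_sparql()]
#' @export
encode_sparql <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  hit <- RESERVED_SEQS[vapply(RESERVED_SEQS, grepl, logical(1), x = query,
                              fixed = TRUE)]
  if (length(hit)) {
    stop(sprintf("query contains reserved sequence %s", dQuote(hit[1])))
  }
  out <- map_outside_literals(query, function(seg) {
    gsub("\\?([A-Za-z_][A-Za-z0-9_]*)", "var_\\1", seg)
  })
  for (ch in names(CHAR_MAP)) {
    out <- gsub(ch, CHAR_MAP[[ch]], out, fixed = TRUE)
  }
  out
}

#' Decode a model-emitted SPARQL query
#'
#' Exact inverse of [encode_sparql()].  Dangling entity fragments (an
#' `&lt`/`&gt`/`&lcub`/`&rcub` without the terminating `;`) signal malformed
#' model output and raise an error.
#'
#' @param enc Encoded query string.
#' @return The decoded SPARQL text.
#' @export
decode_sparql <- function(enc) {
  stopifnot(is.character(enc), length(enc) == 1L)
  if (grepl("&(lt|gt|lcub|rcub)(?!;)", enc, perl = TRUE)) {
    stop(structure(class = c("chemkgqa_decode_error", "error", "condition"),
                   list(message = "malformed entity fragment in encoded query",
                        call = sys.call(-1))))
  }
  out <- enc
  for (ch in names(CHAR_MAP)) {
    out <- gsub(CHAR_MAP[[ch]], ch, out, fixed = TRUE)
  }
  map_outside_literals(out, function(seg) {
    gsub("(?<![A-Za-z0-9_])var_([A-Za-z_][A-Za-z0-9_]*)", "?\\1", seg,
         perl = TRUE)
  })
}

# Apply `fn` to the segments of `x` that lie outside double-quoted literals.
map_outside_literals <- function(x, fn) {
  m <- gregexpr('"(?:[^"\\\\]|\\\\.)*"', x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(fn(x))
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  pieces <- character()
  pos <- 1L
  for (k in seq_along(starts)) {
    if (starts[k] > pos) {
      pieces <- c(pieces, fn(substr(x, pos, starts[k] - 1L)))
    }
    pieces <- c(pieces, substr(x, starts[k], ends[k]))
    pos <- ends[k] + 1L
  }
  if (pos <= nchar(x)) pieces <- c(pieces, fn(substr(x, pos, nchar(x))))
  paste(pieces, collapse = "")
}
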