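# Preprocessing of input questions: rewriting physical quantities to SI
# units (the unit system of the knowledge graph) and prepending the
# translation instruction prompt.

TRANSLATE_PROMPT <- "translate to SPARQL: "

#' Default unit lexicon
#'
#' Maps unit surface forms to an affine conversion to the SI unit of their
#' dimension: `si_value = value * scale + offset`.  Ships temperature
#' (degrees Celsius and Fahrenheit, kelvin) and pressure (atm, bar, mmHg,
#' kPa, Pa); extend by `rbind()`-ing rows with the same columns.
#'
#' @return A data frame of class `unit_lexicon` with columns `surface`,
#'   `dimension`, `scale`, `offset`, `si`.
#' @export
default_unit_lexicon <- function() {
  lex <- rbind(
    data.frame(surface = c("°C", "degrees Celsius", "degree Celsius",
                           "Celsius", "deg C"),
               dimension = "temperature", scale = 1, offset = 273.15, si = "K"),
    data.frame(surface = c("°F", "degrees Fahrenheit", "degree Fahrenheit",
                           "Fahrenheit", "deg F"),
               dimension = "temperature", scale = 5 / 9,
               offset = 459.67 * 5 / 9, si = "K"),
    data.frame(surface = c("K", "kelvin"),
               dimension = "temperature", scale = 1, offset = 0, si = "K"),
    data.frame(surface = "atm", dimension = "pressure",
               scale = 101325, offset = 0, si = "Pa"),
    data.frame(surface = "bar", dimension = "pressure",
               scale = 1e5, offset = 0, si = "Pa"),
    data.frame(surface = "mmHg", dimension = "pressure",
               scale = 133.322387415, offset = 0, si = "Pa"),
    data.frame(surface = "kPa", dimension = "pressure",
               scale = 1000, offset = 0, si = "Pa"),
    data.frame(surface = "Pa", dimension = "pressure",
               scale = 1, offset = 0, si = "Pa"))
  structure(lex, class = c("unit_lexicon", "data.frame"))
}

.NUM_RE <- "[+-]?[0-9]+(?:\\.[0-9]+)?"

#' Convert quantity mentions in a question to SI units
#'
#' Every `number unit` mention whose unit appears in the lexicon is
#' rewritten in the SI unit of its dimension; shared-unit ranges
#' (`between X and Y <unit>`) convert both numbers.  Text without
#' quantities, and quantities with unknown units, pass through unchanged.
#'
#' @param question Question text.
#' @param lexicon A `unit_lexicon`; see [default_unit_lexicon()].
#' @return An object of class `preprocessed_question`: a list with `text`
#'   (the rewritten question, without the instruction prompt),
#'   `conversions` (data frame: original, converted, dimension) and
#'   `original`.
#' @export
convert_units <- function(question, lexicon = default_unit_lexicon()) {
  stopifnot(is.character(question), length(question) == 1L, nzchar(question))
  text <- question
  conv <- list()
  # longest surface forms first so "degrees Celsius" wins over "Celsius"
  lex <- lexicon[order(-nchar(lexicon$surface)), , drop = FALSE]
  for (i in seq_len(nrow(lex))) {
    row <- lex[i, ]
    if (row$scale == 1 && row$offset == 0) next   # already SI
    tail_guard <- if (grepl("[A-Za-z]$", row$surface)) "(?![A-Za-z])" else ""
    surf_re <- paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", row$surface),
                      tail_guard)
    convert_one <- function(v) v * row$scale + row$offset
    # ranges sharing one unit: "between 100 and 120 <unit>"
    range_re <- paste0("between\\s+(", .NUM_RE, ")\\s+and\\s+(", .NUM_RE,
                       ")\\s*", surf_re)
    text <- regex_replace(text, range_re, function(m) {
      nums <- as.numeric(regmatches(m, gregexpr(.NUM_RE, m))[[1]][1:2])
      rep <- sprintf("between %s and %s %s",
                     format_quantity(convert_one(nums[1])),
                     format_quantity(convert_one(nums[2])), row$si)
      conv[[length(conv) + 1L]] <<- data.frame(original = m, converted = rep,
                                               dimension = row$dimension)
      rep
    })
    single_re <- paste0("(", .NUM_RE, ")\\s*", surf_re)
    text <- regex_replace(text, single_re, function(m) {
      num <- as.numeric(regmatches(m, regexpr(.NUM_RE, m)))
      rep <- sprintf("%s %s", format_quantity(convert_one(num)), row$si)
      conv[[length(conv) + 1L]] <<- data.frame(original = m, converted = rep,
                                               dimension = row$dimension)
      rep
    })
  }
  conversions <- if (length(conv)) do.call(rbind, conv)
                 else data.frame(original = character(),
                                 converted = character(),
                                 dimension = character())
  structure(list(text = text, conversions = conversions,
                 original = question),
            class = "preprocessed_question")
}

#' Prepend the translation instruction prompt
#'
#' @param text Question text or a `preprocessed_question`.
#' @param prompt Instruction prompt (defaults to `"translate to SPARQL: "`).
#' @return `prompt` followed by the text.  Applied once by the pipeline;
#'   callers must not apply it twice.
#' @export
prepend_prompt <- function(text, prompt = TRANSLATE_PROMPT) {
  if (inherits(text, "preprocessed_question")) text <- text$text
  paste0(prompt, text)
}

# gsub with a function replacement (applied left to right, non-overlapping)
regex_replace <- function(x, pattern, fn) {
  m <- gregexpr(pattern, x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(x)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  pieces <- character()
  pos <- 1L
  for (k in seq_along(starts)) {
    pieces <- c(pieces, substr(x, pos, starts[k] - 1L),
                fn(substr(x, starts[k], ends[k])))
    pos <- ends[k] + 1L
  }
  paste(c(pieces, substr(x, pos, nchar(x))), collapse = "")
}
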