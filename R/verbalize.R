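# Verbalization of canonical queries into natural-language questions, and
# paraphrase collection with the entity-preservation rule.

VERBALIZATION_FORMS <- c("interrogative", "imperative", "keyword")

join_and <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  paste(paste(x[-n], collapse = ", "), "and", x[n])
}

filter_phrase <- function(f) {
  switch(f$op,
    higher = paste("higher than", format_quantity(f$a)),
    lower = paste("lower than", format_quantity(f$a)),
    inside = sprintf("inside the range between %s and %s",
                     format_quantity(f$a), format_quantity(f$b)),
    outside = sprintf("outside the range between %s and %s",
                      format_quantity(f$a), format_quantity(f$b)),
    around = paste("around", format_quantity(f$a)))
}

#' Verbalize a canonical query
#'
#' Deterministic template realization of a canonical query in one of three
#' forms: interrogative ("what is the charge of benzene?"), imperative
#' ("tell me about the charge of benzene.") or keyword search ("charge of
#' benzene").  Grounded entity surface forms appear verbatim; numeric
#' filters verbalize as "higher than a", "inside the range between a and
#' b", "around a", etc., with bounds in the order they were generated.
#'
#' @param q A `canonical_query` from [ground_query()].
#' @param form One of `"interrogative"`, `"imperative"`, `"keyword"`.
#' @return The question text.
#' @export
verbalize <- function(q, form = "interrogative") {
  stopifnot(inherits(q, "canonical_query"))
  form <- match.arg(form, VERBALIZATION_FORMS)
  m <- q$meta
  switch(m$kind,
    property_lookup = verbalize_lookup(m$props, m$species, form),
    species_search = verbalize_search(m$conditions, form),
    class_property = verbalize_class(m$props, m$class, form))
}

verbalize_lookup <- function(props, species, form) {
  props <- join_and(props)
  switch(form,
    interrogative = sprintf("what %s the %s of %s?",
                            if (grepl(" and ", props)) "are" else "is",
                            props, species),
    imperative = sprintf("tell me about the %s of %s.", props, species),
    keyword = sprintf("%s of %s", props, species))
}

condition_phrase <- function(cond) {
  switch(cond$type,
    use = sprintf("can be used as a %s", cond$surface),
    class = sprintf("are classified as %s", cond$surface),
    label = sprintf("have a %s of %s", cond$label, cond$surface),
    numeric = sprintf("have a %s %s", cond$label, filter_phrase(cond$filter)))
}

verbalize_search <- function(conditions, form) {
  conds <- join_and(vapply(conditions, condition_phrase, character(1)))
  switch(form,
    interrogative = sprintf("what are the chemical species that %s?", conds),
    imperative = sprintf("find chemical species that %s.", conds),
    keyword = sprintf("chemical species that %s", conds))
}

verbalize_class <- function(props, class_surface, form) {
  props <- join_and(props)
  switch(form,
    interrogative = sprintf("what %s the %s of chemical species classified as %s?",
                            if (grepl(" and ", props)) "are" else "is",
                            props, class_surface),
    imperative = sprintf("tell me about the %s of chemical species classified as %s.",
                         props, class_surface),
    keyword = sprintf("%s of chemical species classified as %s",
                      props, class_surface))
}

# ---- paraphrasing ----------------------------------------------------------

#' Collect paraphrases of a canonical question
#'
#' Calls a paraphrase provider and keeps only candidates that preserve
#' every grounded entity mention verbatim (entity linking is performed by
#' exact string matching inside the query, so entity surface forms must
#' not be rephrased).  Keyword-form questions are never paraphrased; the
#' provider is not called for them.  Provider failures yield an empty list
#' so the canonical question remains usable.
#'
#' @param canonical The canonical question text.
#' @param entities Character vector of grounded entity surface forms.
#' @param provider A function `(text, n) -> character()` of candidates,
#'   e.g. [rule_paraphraser()].
#' @param n Maximum number of paraphrases to keep.
#' @param form Verbalization form of `canonical`.
#' @return Character vector of accepted paraphrases (possibly empty).
#' @export
collect_paraphrases <- function(canonical, entities, provider, n = 5,
                                form = "interrogative") {
  form <- match.arg(form, VERBALIZATION_FORMS)
  if (form == "keyword") return(character())
  cands <- tryCatch(provider(canonical, n), error = function(e) character())
  if (!length(cands)) return(character())
  cands <- utils::head(unique(cands[nzchar(cands) & cands != canonical]), n)
  keep <- vapply(cands, function(cand) {
    all(vapply(entities, grepl, logical(1), x = cand, fixed = TRUE))
  }, logical(1))
  unname(cands[keep])
}

#' Deterministic rule-based paraphrase provider
#'
#' A small synonym-table rewriter standing behind the paraphrase-provider
#' interface: each rule rewrites the sentence frame (never entity
#' mentions), so candidates stay faithful to the query intent.  A remote
#' LLM provider can be supplied instead wherever a provider function is
#' accepted.
#'
#' @return A provider function `(text, n) -> character()`.
#' @export
rule_paraphraser <- function() {
  rules <- list(
    c("^what is the ", "could you tell me the "),
    c("^what is the ", "i would like to know the "),
    c("^what are the chemical species that ", "which chemical species "),
    c("^what are the ", "could you list the "),
    c("^tell me about the ", "show me the "),
    c("^tell me about the ", "give me details on the "),
    c("^find chemical species that ", "search for chemical species that "),
    c("\\?$", ", please?"))
  function(text, n) {
    out <- character()
    for (r in rules) {
      if (grepl(r[1], text)) out <- c(out, sub(r[1], r[2], text))
    }
    utils::head(unique(out), n)
  }
}
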