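# Canonical logical-form generation: schema subgraphs rooted at the species
# class are sampled, grounded against instance data, and optionally
# constrained with comparative filters, yielding executable SPARQL SELECT
# queries of three intents:
#   property_lookup  one-hop lookups about a grounded species
#   species_search   species satisfying property/use/class conditions
#   class_property   two-hop: properties of species in a chemical class

QUERY_INTENTS <- c("property_lookup", "species_search", "class_property")
FILTER_OPS <- c("higher", "lower", "inside", "outside", "around")

#' Comparative filter on a numeric query variable
#'
#' The five comparative operators: `higher` (x > a), `lower` (x < a),
#' `inside` (a < x < b), `outside` (x < a or x > b) and `around`
#' (0.9a < x < 1.1a, defined for a > 0).  `a` and `b` are kept in the
#' order the user supplied them; [build_filter()] normalizes bounds.
#'
#' @param op One of `"higher"`, `"lower"`, `"inside"`, `"outside"`,
#'   `"around"`.
#' @param a Numeric threshold.
#' @param b Second threshold; required for (and only allowed with)
#'   `inside`/`outside`.
#' @param variable Query-variable name the filter constrains (without `?`).
#' @return A `comparative_filter` object.
#' @export
comparative_filter <- function(op, a, b = NULL, variable = "x") {
  op <- match.arg(op, FILTER_OPS)
  stopifnot(is.numeric(a), length(a) == 1L)
  if (op %in% c("inside", "outside")) {
    if (is.null(b)) stop(sprintf("operator %s requires both bounds a and b", op))
    stopifnot(is.numeric(b), length(b) == 1L)
  } else if (!is.null(b)) {
    stop(sprintf("operator %s takes a single threshold a", op))
  }
  if (op == "around" && a <= 0) {
    stop("operator around is defined only for a > 0")
  }
  structure(list(op = op, a = a, b = b,
                 variable = sub("^\\?", "", variable)),
            class = "comparative_filter")
}

#' Render a comparative filter as a SPARQL FILTER clause
#'
#' Bounds for `inside`/`outside` are normalized so the smaller of (a, b) is
#' the lower bound; `around` expands to the band from 0.9a to 1.1a.
#'
#' @param f A [comparative_filter()].
#' @return FILTER clause text, e.g. `FILTER ( ?BoilingPointValue > 373 )`.
#' @export
build_filter <- function(f) {
  stopifnot(inherits(f, "comparative_filter"))
  v <- paste0("?", f$variable)
  b <- filter_bounds(f)
  body <- switch(f$op,
    higher = sprintf("%s > %s", v, format_quantity(b[1])),
    lower = sprintf("%s < %s", v, format_quantity(b[1])),
    inside = sprintf("%s > %s && %s < %s", v, format_quantity(b[1]),
                     v, format_quantity(b[2])),
    outside = sprintf("%s < %s || %s > %s", v, format_quantity(b[1]),
                      v, format_quantity(b[2])),
    around = sprintf("%s > %s && %s < %s", v, format_quantity(b[1]),
                     v, format_quantity(b[2])))
  sprintf("FILTER ( %s )", body)
}

#' Numeric bounds realized by a comparative filter
#'
#' @param f A [comparative_filter()].
#' @return For `higher`/`lower` the single threshold; for `inside`/`outside`
#'   the sorted pair (lower, upper); for `around` the pair
#'   `c(0.9 * a, 1.1 * a)`.
#' @export
filter_bounds <- function(f) {
  stopifnot(inherits(f, "comparative_filter"))
  switch(f$op,
    higher = f$a,
    lower = f$a,
    inside = sort(c(f$a, f$b)),
    outside = sort(c(f$a, f$b)),
    around = c(0.9 * f$a, 1.1 * f$a))
}

# does `x` satisfy the filter?
filter_satisfied <- function(f, x) {
  b <- filter_bounds(f)
  switch(f$op,
    higher = x > b[1],
    lower = x < b[1],
    inside = x > b[1] & x < b[2],
    outside = x < b[1] | x > b[2],
    around = x > b[1] & x < b[2])
}

#' Entity-linking block for a chemical species
#'
#' Species are linked inside the query by exact string matching of the
#' given surface form against the value of any of the species' identifiers
#' (of any identifier subtype), via a VALUES binding and a
#' variable-predicate triple pattern.
#'
#' @param surface Non-empty identifier surface form (IUPAC name, SMILES,
#'   molecular formula, ...).
#' @return A character block of SPARQL lines.
#' @export
build_species_grounding <- function(surface) {
  stopifnot(is.character(surface), length(surface) == 1L)
  if (!nzchar(surface)) stop("species surface form must be non-empty")
  paste(
    sprintf('VALUES (?species) { ("%s") }', escape_literal(surface)),
    "?SpeciesIRI ?hasIdentifier ?IdentifierIRI .",
    "?IdentifierIRI os:value ?species .",
    sep = "\n")
}

# ---- subgraph sampling -----------------------------------------------------

#' Sample a schema subgraph rooted at the species class
#'
#' Edges are drawn without replacement from the relations whose domain is
#' the species class.  The out-degree of the species root varies from 1 to
#' 3; requests outside that range are an error.
#'
#' @param schema An `ontology_schema`.
#' @param out_degree Number of edges (1 to 3).
#' @return A `schema_subgraph`: list with `root`, `edges` (rows of
#'   `schema$relations`), `out_degree` and the originating `schema`.
#' @export
sample_subgraph <- function(schema, out_degree) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (!is.numeric(out_degree) || length(out_degree) != 1L ||
      out_degree < 1 || out_degree > 3) {
    stop("out_degree must lie in [1, 3]")
  }
  rels <- relations_from(schema, schema$species_class)
  if (nrow(rels) < out_degree) {
    stop(sprintf("schema has only %d relations from the species class",
                 nrow(rels)))
  }
  idx <- sample.int(nrow(rels), out_degree)
  structure(list(root = schema$species_class,
                 edges = rels[idx, , drop = FALSE],
                 out_degree = as.integer(out_degree),
                 schema = schema),
            class = "schema_subgraph")
}

# edge taxonomy: identifier / numeric / class / use / label
edge_kind <- function(schema, edge) {
  if (edge$range %in% schema$identifier_classes) return("identifier")
  if (edge$numeric) return("numeric")
  ln <- local_name(edge$range)
  if (ln == "ChemicalClass") return("class")
  if (ln == "Use") return("use")
  "label"
}

subgraph_kinds <- function(sub) {
  vapply(seq_len(nrow(sub$edges)), function(i)
    edge_kind(sub$schema, sub$edges[i, ]), character(1))
}

#' Is a query intent compatible with a subgraph?
#'
#' `species_search` requires every edge to be a groundable condition (use,
#' chemical class) or a numeric property; `class_property` requires a
#' chemical-class edge plus at least one other edge.
#'
#' @param sub A `schema_subgraph`.
#' @param intent One of the three query intents.
#' @return Logical scalar.
#' @export
intent_compatible <- function(sub, intent) {
  intent <- match.arg(intent, QUERY_INTENTS)
  kinds <- subgraph_kinds(sub)
  switch(intent,
    property_lookup = TRUE,
    species_search = all(kinds %in% c("numeric", "class", "use", "label")),
    class_property = any(kinds == "class") && sub$out_degree >= 2L)
}

# variable-name base for a relation: os:hasBoilingPoint -> "BoilingPoint"
rel_base <- function(iri) sub("^has", "", local_name(iri))

# value-bearing predicate of an edge target
value_predicate <- function(kind) {
  if (kind %in% c("numeric", "identifier")) "os:value" else "rdfs:label"
}
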