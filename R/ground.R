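# Grounding sampled schema subgraphs against instance data.  Groundings are
# drawn from the knowledge graph so every generated query has at least one
# answer; numeric filters are anchored at an actual property value of the
# anchor species.

OS_PREFIX <- "http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#"

kg_triples <- function(kg) {
  stopifnot(inherits(kg, "kg_store"))
  if (kg$backing != "memory") {
    stop("grounding requires an in-memory kg_store")
  }
  kg$triples
}

kg_species <- function(kg, schema) {
  tr <- kg_triples(kg)
  rdf_type <- paste0(schema$prefixes[["rdf"]], "type")
  sort(unique(tr$s[tr$p == rdf_type & tr$o == schema$species_class]))
}

# lexical values reachable from `species` over `rel_iri` then value/label
kg_edge_values <- function(kg, schema, species, rel_iri, value_p) {
  tr <- kg_triples(kg)
  nodes <- tr$o[tr$s == species & tr$p == rel_iri]
  vp <- expand_pname(value_p, schema$prefixes)
  vals <- tr$o_lex[tr$s %in% nodes & tr$p == vp & tr$o_kind == "literal"]
  unique(vals[!is.na(vals)])
}

kg_identifier_values <- function(kg, schema, species) {
  tr <- kg_triples(kg)
  id_rels <- schema$relations$iri[schema$relations$range %in%
                                    schema$identifier_classes]
  out <- character()
  for (r in id_rels) {
    out <- c(out, kg_edge_values(kg, schema, species, r, "os:value"))
  }
  unique(out)
}

# pname form of a full IRI under the schema prefixes (os: etc.)
pname_of <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    if (startsWith(iri, prefixes[[p]])) {
      return(paste0(p, ":", substring(iri, nchar(prefixes[[p]]) + 1L)))
    }
  }
  paste0("<", iri, ">")
}

#' Ground a schema subgraph into a canonical SPARQL query
#'
#' Instantiates a sampled subgraph according to the query intent:
#' `property_lookup` grounds the species node (by one of its identifier
#' surface forms) and asks for the values of the sampled relations;
#' `species_search` asks for species, grounding use/class conditions from
#' KG instances and constraining every numeric property with one
#' comparative filter sampled uniformly from the five operators;
#' `class_property` grounds a chemical class and asks for properties of its
#' member species (two-hop).  Grounding literals are drawn from the KG, so
#' the query has at least one answer.
#'
#' @param sub A `schema_subgraph` from [sample_subgraph()].
#' @param intent Query intent; see [intent_compatible()].
#' @param kg An in-memory `kg_store` with instance data.
#' @return A `canonical_query`: list with `sparql`, `intent`, `relations`,
#'   `filters`, `groundings`, `n_relations` and verbalization metadata.
#' @export
ground_query <- function(sub, intent, kg) {
  stopifnot(inherits(sub, "schema_subgraph"))
  intent <- match.arg(intent, QUERY_INTENTS)
  if (!intent_compatible(sub, intent)) {
    stop(sprintf("intent %s incompatible with sampled subgraph", intent))
  }
  schema <- sub$schema
  kinds <- subgraph_kinds(sub)
  switch(intent,
    property_lookup = ground_property_lookup(sub, kinds, kg, schema),
    species_search = ground_species_search(sub, kinds, kg, schema),
    class_property = ground_class_property(sub, kinds, kg, schema))
}

new_canonical_query <- function(sparql, intent, relations, filters,
                                groundings, meta) {
  ast <- parse_sparql(sparql)   # generated queries must parse
  structure(list(sparql = sparql, intent = intent, relations = relations,
                 filters = filters, groundings = groundings,
                 n_relations = length(relations), meta = meta),
            class = "canonical_query")
}

#' @export
print.canonical_query <- function(x, ...) {
  cat(sprintf("<canonical_query> intent=%s, %d relation(s)\n",
              x$intent, x$n_relations))
  cat(x$sparql, "\n")
  invisible(x)
}

# an anchor species holding instances for every edge of the subgraph
pick_anchor <- function(sub, kinds, kg, schema, need_identifier = FALSE) {
  candidates <- kg_species(kg, schema)
  if (!length(candidates)) stop("KG holds no species instances")
  candidates <- sample(candidates)
  for (sp in candidates) {
    ok <- TRUE
    for (i in seq_len(nrow(sub$edges))) {
      vals <- kg_edge_values(kg, schema, sp, sub$edges$iri[i],
                             value_predicate(kinds[i]))
      if (!length(vals)) {
        ok <- FALSE
        break
      }
    }
    if (ok && need_identifier && !length(kg_identifier_values(kg, schema, sp))) {
      ok <- FALSE
    }
    if (ok) return(sp)
  }
  stop("KG lacks instances to ground the sampled subgraph")
}

property_block <- function(base, rel_pname, value_p) {
  c(sprintf("?SpeciesIRI %s ?%sIRI .", rel_pname, base),
    sprintf("?%sIRI %s ?%sValue .", base, value_p, base))
}

ground_property_lookup <- function(sub, kinds, kg, schema) {
  anchor <- pick_anchor(sub, kinds, kg, schema, need_identifier = TRUE)
  surface <- sample(kg_identifier_values(kg, schema, anchor), 1L)
  bases <- rel_base(sub$edges$iri)
  lines <- strsplit(build_species_grounding(surface), "\n")[[1]]
  select_vars <- character()
  for (i in seq_len(nrow(sub$edges))) {
    vp <- value_predicate(kinds[i])
    lines <- c(lines, property_block(bases[i],
                                     pname_of(sub$edges$iri[i], schema$prefixes),
                                     vp))
    select_vars <- c(select_vars, sprintf("?%sValue", bases[i]))
  }
  sparql <- paste(c(paste("SELECT", paste(select_vars, collapse = " ")),
                    "WHERE {", lines, "}"), collapse = "\n")
  new_canonical_query(
    sparql, "property_lookup", sub$edges$iri, list(),
    list(list(role = "species", text = surface)),
    list(kind = "property_lookup", props = sub$edges$label, species = surface))
}

ground_species_search <- function(sub, kinds, kg, schema) {
  anchor <- pick_anchor(sub, kinds, kg, schema)
  bases <- rel_base(sub$edges$iri)
  lines <- character()
  filters <- list()
  groundings <- list()
  conditions <- list()
  for (i in seq_len(nrow(sub$edges))) {
    base <- bases[i]
    vp <- value_predicate(kinds[i])
    rel_pn <- pname_of(sub$edges$iri[i], schema$prefixes)
    vals <- kg_edge_values(kg, schema, anchor, sub$edges$iri[i], vp)
    if (kinds[i] == "numeric") {
      v <- as.numeric(sample(vals, 1L))
      f <- sample_filter(v, paste0(base, "Value"))
      filters[[length(filters) + 1L]] <- f
      lines <- c(lines, property_block(base, rel_pn, vp))
      conditions[[length(conditions) + 1L]] <-
        list(type = "numeric", label = sub$edges$label[i], filter = f)
    } else {
      surface <- sample(vals, 1L)
      lines <- c(lines,
                 sprintf('VALUES (?%sValue) { ("%s") }', base,
                         escape_literal(surface)),
                 property_block(base, rel_pn, vp))
      groundings[[length(groundings) + 1L]] <-
        list(role = tolower(kinds[i]), text = surface)
      conditions[[length(conditions) + 1L]] <-
        list(type = kinds[i], label = sub$edges$label[i], surface = surface)
    }
  }
  lines <- c(lines, vapply(filters, build_filter, character(1)))
  sparql <- paste(c("SELECT ?SpeciesIRI", "WHERE {", lines, "}"),
                  collapse = "\n")
  new_canonical_query(
    sparql, "species_search", sub$edges$iri, filters, groundings,
    list(kind = "species_search", conditions = conditions))
}

ground_class_property <- function(sub, kinds, kg, schema) {
  anchor <- pick_anchor(sub, kinds, kg, schema)
  class_i <- which(kinds == "class")[1]
  other <- setdiff(seq_len(nrow(sub$edges)), class_i)
  class_vals <- kg_edge_values(kg, schema, anchor, sub$edges$iri[class_i],
                               "rdfs:label")
  class_surface <- sample(class_vals, 1L)
  bases <- rel_base(sub$edges$iri)
  lines <- c(sprintf('VALUES (?ChemicalClassValue) { ("%s") }',
                     escape_literal(class_surface)),
             property_block(bases[class_i],
                            pname_of(sub$edges$iri[class_i], schema$prefixes),
                            "rdfs:label"))
  select_vars <- character()
  for (i in other) {
    vp <- value_predicate(kinds[i])
    lines <- c(lines, property_block(bases[i],
                                     pname_of(sub$edges$iri[i], schema$prefixes),
                                     vp))
    select_vars <- c(select_vars, sprintf("?%sValue", bases[i]))
  }
  sparql <- paste(c(paste("SELECT", paste(select_vars, collapse = " ")),
                    "WHERE {", lines, "}"), collapse = "\n")
  new_canonical_query(
    sparql, "class_property", sub$edges$iri, list(),
    list(list(role = "class", text = class_surface)),
    list(kind = "class_property", props = sub$edges$label[other],
         class = class_surface))
}

# One comparative operator, uniform over the five choices, anchored so the
# anchor value `v` satisfies the filter (an answer is guaranteed to exist).
# `around` requires a positive threshold and is skipped for v <= 0.
sample_filter <- function(v, variable) {
  ops <- if (v > 0) FILTER_OPS else setdiff(FILTER_OPS, "around")
  op <- sample(ops, 1L)
  delta <- max(1, abs(v) * 0.15)
  rnd <- function(x) round(x, 1)
  maybe_swap <- function(a, b) if (stats::runif(1) < 0.5) c(a, b) else c(b, a)
  f <- switch(op,
    higher = comparative_filter("higher", min(rnd(v - delta), v - delta),
                                variable = variable),
    lower = comparative_filter("lower", max(rnd(v + delta), v + delta),
                               variable = variable),
    inside = {
      ab <- maybe_swap(min(rnd(v - delta), v - delta),
                       max(rnd(v + delta), v + delta))
      comparative_filter("inside", ab[1], ab[2], variable = variable)
    },
    outside = {
      lo_hi <- if (stats::runif(1) < 0.5) {
        c(max(rnd(v + delta), v + delta), rnd(v + 3 * delta))
      } else {
        c(rnd(v - 3 * delta), min(rnd(v - delta), v - delta))
      }
      ab <- maybe_swap(lo_hi[1], lo_hi[2])
      comparative_filter("outside", ab[1], ab[2], variable = variable)
    },
    around = comparative_filter("around", v, variable = variable))
  stopifnot(filter_satisfied(f, v))
  f
}
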