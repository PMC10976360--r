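# Ontology schema representation and SPARQL SELECT execution.
#
# The schema mirrors an OntoSpecies-style ontology: chemical species with
# identifier subtypes (IUPAC name, SMILES, molecular formula), numeric
# properties whose values carry units and optional reference states,
# chemical-class membership and use annotations.

XSD_NUMERIC <- paste0("http://www.w3.org/2001/XMLSchema#",
                      c("decimal", "integer", "double", "float"))

#' Load an ontology schema from a Turtle document
#'
#' Extracts class and relation definitions from an ontology document.
#' Classes are subjects typed `owl:Class`; relations are subjects typed
#' `owl:ObjectProperty` with `rdfs:domain` and `rdfs:range`.  A relation is
#' flagged numeric when its range class carries an `os:value` exemplar typed
#' as an XSD decimal or integer in the ontology; the flag can be overridden
#' per relation via `numeric_override`.
#'
#' @param path Path to a Turtle ontology file, or the document text itself.
#' @param species_class Optional IRI (or local name) of the species class;
#'   by default the class whose local name is `Species`.
#' @param identifier_class Local name or IRI of the identifier superclass
#'   used to enumerate identifier subtypes (default `Identifier`).  The
#'   subclasses can also be listed explicitly via `identifier_classes`.
#' @param identifier_classes Optional character vector of identifier class
#'   IRIs, overriding derivation from the subclass hierarchy.
#' @param numeric_override Optional named logical vector keyed by relation
#'   IRI, overriding the numeric flag.
#' @return An object of class `ontology_schema` with elements `classes`
#'   (data frame: iri, label, parent), `relations` (data frame: iri, label,
#'   domain, range, numeric, plus a list column `surface_forms`),
#'   `species_class`, `identifier_classes` and `prefixes`.
#' @export
load_schema <- function(path, species_class = NULL,
                        identifier_class = "Identifier",
                        identifier_classes = NULL,
                        numeric_override = NULL) {
  tt <- parse_turtle(path)
  pre <- tt$prefixes
  rdf_type <- paste0(pre[["rdf"]], "type")
  rdfs <- pre[["rdfs"]]
  os <- pre[["os"]]

  class_iris <- tt_subjects(tt, rdf_type, paste0(pre[["owl"]], "Class"))
  if (!length(class_iris)) stop("no classes found in ontology document")
  get_label <- function(iri) {
    rows <- tt_objects(tt, iri, paste0(rdfs, "label"))
    if (nrow(rows)) rows$o_lex[1] else local_name(iri)
  }
  get_parent <- function(iri) {
    rows <- tt_objects(tt, iri, paste0(rdfs, "subClassOf"))
    if (nrow(rows)) rows$o[1] else NA_character_
  }
  classes <- data.frame(
    iri = sort(class_iris),
    label = vapply(sort(class_iris), get_label, character(1)),
    parent = vapply(sort(class_iris), get_parent, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (anyDuplicated(classes$iri)) stop("duplicate class IRIs in ontology")
  bad_parent <- !is.na(classes$parent) & !classes$parent %in% classes$iri
  if (any(bad_parent)) {
    stop(sprintf("class %s has undefined parent %s",
                 classes$iri[bad_parent][1], classes$parent[bad_parent][1]))
  }

  rel_iris <- sort(tt_subjects(tt, rdf_type, paste0(pre[["owl"]], "ObjectProperty")))
  if (anyDuplicated(rel_iris)) stop("duplicate relation IRIs in ontology")
  one_obj <- function(iri, p) {
    rows <- tt_objects(tt, iri, p)
    if (nrow(rows)) rows$o[1] else NA_character_
  }
  # numeric ranges: class carries an os:value exemplar typed decimal/integer
  range_numeric <- function(range_iri) {
    rows <- tt_objects(tt, range_iri, paste0(os, "value"))
    any(rows$o_kind == "literal" & rows$o_dt %in% XSD_NUMERIC)
  }
  rels <- lapply(rel_iris, function(iri) {
    lab <- get_label(iri)
    if (!nzchar(lab)) stop(sprintf("relation %s has an empty label", iri))
    alt <- tt_objects(tt, iri, paste0(pre[["skos"]], "altLabel"))$o_lex
    dom <- one_obj(iri, paste0(rdfs, "domain"))
    rng <- one_obj(iri, paste0(rdfs, "range"))
    for (ref in c(domain = dom, range = rng)) {
      if (is.na(ref) || !ref %in% classes$iri) {
        stop(sprintf("relation %s refers to undefined %s class %s",
                     iri, if (identical(ref, dom)) "domain" else "range",
                     if (is.na(ref)) "(missing)" else ref))
      }
    }
    num <- range_numeric(rng)
    if (!is.null(numeric_override) && iri %in% names(numeric_override)) {
      num <- isTRUE(numeric_override[[iri]])
    }
    list(iri = iri, label = lab, surface_forms = unique(c(lab, alt)),
         domain = dom, range = rng, numeric = num)
  })
  relations <- data.frame(
    iri = vapply(rels, `[[`, character(1), "iri"),
    label = vapply(rels, `[[`, character(1), "label"),
    domain = vapply(rels, `[[`, character(1), "domain"),
    range = vapply(rels, `[[`, character(1), "range"),
    numeric = vapply(rels, `[[`, logical(1), "numeric"),
    row.names = NULL, stringsAsFactors = FALSE)
  relations$surface_forms <- lapply(rels, `[[`, "surface_forms")

  resolve_class <- function(x) {
    if (is.null(x)) return(NULL)
    hit <- if (x %in% classes$iri) x else classes$iri[local_name(classes$iri) == x]
    if (!length(hit)) stop(sprintf("class %s not defined in ontology", x))
    hit[1]
  }
  sp <- resolve_class(species_class)
  if (is.null(sp)) {
    sp <- classes$iri[local_name(classes$iri) == "Species"]
    if (!length(sp)) stop("no species class found; pass species_class")
    sp <- sp[1]
  }
  if (is.null(identifier_classes)) {
    idsuper <- resolve_class(identifier_class)
    identifier_classes <- classes$iri[!is.na(classes$parent) &
                                        classes$parent == idsuper]
  } else {
    missing_ids <- setdiff(identifier_classes, classes$iri)
    if (length(missing_ids)) {
      stop(sprintf("identifier class %s not defined", missing_ids[1]))
    }
  }

  structure(list(classes = classes, relations = relations,
                 species_class = sp,
                 identifier_classes = sort(identifier_classes),
                 prefixes = pre),
            class = "ontology_schema")
}

local_name <- function(iri) sub("^.*[#/]", "", iri)

#' @export
print.ontology_schema <- function(x, ...) {
  cat(sprintf("<ontology_schema> %d classes, %d relations\n",
              nrow(x$classes), nrow(x$relations)))
  cat("species class:", x$species_class, "\n")
  cat("identifier classes:", paste(local_name(x$identifier_classes),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Relations whose domain is a given class
#'
#' @param schema An `ontology_schema`.
#' @param cls Class IRI (or local name) defined in the schema.
#' @return The subset of `schema$relations` with `domain == cls`, ordered by
#'   relation IRI.
#' @export
relations_from <- function(schema, cls) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (!cls %in% schema$classes$iri) {
    hit <- schema$classes$iri[local_name(schema$classes$iri) == cls]
    if (!length(hit)) stop(sprintf("class %s not defined in schema", cls))
    cls <- hit[1]
  }
  out <- schema$relations[schema$relations$domain == cls, , drop = FALSE]
  out[order(out$iri), , drop = FALSE]
}

# ---- store -----------------------------------------------------------------

#' Create a knowledge-graph store
#'
#' Either an in-memory triple set loaded from Turtle/N-Triples text or file,
#' or a remote SPARQL 1.1 endpoint address.  The `prologue` (namespace
#' prefix declarations) is injected before query execution, so dataset
#' queries can omit PREFIX declarations.
#'
#' @param instances Turtle/N-Triples text or file path (in-memory backing).
#' @param endpoint URL of a SPARQL endpoint (remote backing).
#' @param prologue Named character vector of prefix-to-IRI mappings.
#' @return A `kg_store` object.
#' @export
kg_store <- function(instances = NULL, endpoint = NULL,
                     prologue = default_prefixes()) {
  if (is.null(instances) == is.null(endpoint)) {
    stop("provide exactly one of `instances` or `endpoint`")
  }
  if (!is.null(instances)) {
    tt <- parse_turtle(instances)
    structure(list(backing = "memory", triples = tt$triples,
                   prologue = prologue), class = "kg_store")
  } else {
    structure(list(backing = "endpoint", endpoint = endpoint,
                   prologue = prologue), class = "kg_store")
  }
}

#' @export
print.kg_store <- function(x, ...) {
  if (x$backing == "memory") {
    cat(sprintf("<kg_store> in-memory, %d triples\n", nrow(x$triples)))
  } else {
    cat(sprintf("<kg_store> endpoint %s\n", x$endpoint))
  }
  invisible(x)
}

#' Execute a SPARQL SELECT query
#'
#' Parses and evaluates the query against the store.  An empty result table
#' is a valid outcome and is distinguished from a syntax error (signalled as
#' a condition of class `chemkgqa_syntax_error`).
#'
#' @param store A `kg_store`.
#' @param query SPARQL SELECT text.  PREFIX declarations may be omitted;
#'   the store's prologue is injected.
#' @return A data frame with one column per SELECT variable, rows ordered
#'   deterministically.  Literal bindings are returned as their lexical
#'   forms, IRIs as full IRI strings.
#' @export
execute_select <- function(store, query) {
  stopifnot(inherits(store, "kg_store"))
  if (store$backing == "endpoint") {
    return(execute_endpoint(store, query))
  }
  ast <- parse_sparql(query)
  prefixes <- store$prologue
  prefixes[names(ast$prefixes)] <- ast$prefixes
  sol <- eval_group(ast$where, store$triples, prefixes)
  project_solution(sol, ast)
}

project_solution <- function(sol, ast) {
  vars <- sub("^\\?", "", ast$vars)
  out <- lapply(vars, function(v) {
    if (v %in% names(sol)) readable_key(sol[[v]]) else rep(NA_character_, nrow(sol))
  })
  names(out) <- vars
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  if (nrow(df)) {
    if (ast$distinct) df <- unique(df)
    df <- df[do.call(order, c(unname(as.list(df)), list(method = "radix"))), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

readable_key <- function(key) {
  lit <- !is.na(key) & startsWith(key, '"')   # unbound OPTIONAL vars are NA
  out <- key
  out[lit] <- sub('^"(.*)"(\\^\\^.*)?$', "\\1", key[lit])
  out[lit] <- unescape_literal(out[lit])
  out
}

# ---- evaluation of group graph patterns ------------------------------------

eval_group <- function(items, triples, prefixes) {
  sol <- data.frame(matrix(nrow = 1, ncol = 0))
  triples_items <- Filter(function(it) it$type %in% c("triple", "values"), items)
  optionals <- Filter(function(it) it$type == "optional", items)
  filters <- Filter(function(it) it$type == "filter", items)

  for (it in triples_items) {
    part <- if (it$type == "values") values_bindings(it, prefixes)
            else match_pattern(it, triples, prefixes)
    sol <- join_solutions(sol, part, all_x = FALSE)
    if (!nrow(sol)) break
  }
  if (nrow(sol)) {
    for (opt in optionals) {
      part <- eval_group(opt$items, triples, prefixes)
      sol <- join_solutions(sol, part, all_x = TRUE)
    }
    for (f in filters) sol <- apply_filter(sol, f)
  }
  sol
}

values_bindings <- function(item, prefixes) {
  keys <- vapply(item$literals, function(l) term_to_node(l, prefixes)$key,
                 character(1))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- sub("^\\?", "", item$var)
  out
}

match_pattern <- function(tr, triples, prefixes) {
  sel <- rep(TRUE, nrow(triples))
  cols <- list()
  slots <- list(s = tr$s, p = tr$p, o = tr$o)
  colname <- c(s = "s", p = "p", o = "o")
  for (nm in names(slots)) {
    term <- slots[[nm]]
    if (is_var(term)) {
      cols[[var_name(term)]] <- c(cols[[var_name(term)]], colname[[nm]])
    } else {
      key <- term_to_node(term, prefixes)$key
      sel <- sel & triples[[colname[[nm]]]] == key
    }
  }
  hit <- triples[sel, , drop = FALSE]
  out <- data.frame(matrix(nrow = nrow(hit), ncol = 0))
  for (v in names(cols)) {
    slots_v <- cols[[v]]
    out[[v]] <- hit[[slots_v[1]]]
    if (length(slots_v) > 1L) {           # same variable in several positions
      for (sv in slots_v[-1]) out <- out[out[[v]] == hit[[sv]], , drop = FALSE]
    }
  }
  unique(out)
}

join_solutions <- function(x, y, all_x = FALSE) {
  if (!ncol(x)) return(y)
  if (!ncol(y)) return(x)
  by <- intersect(names(x), names(y))
  if (length(by)) {
    merge(x, y, by = by, all.x = all_x, sort = TRUE)
  } else {
    merge(x, y, by = NULL)
  }
}

apply_filter <- function(sol, f) {
  if (!nrow(sol)) return(sol)
  comp_val <- function(term) {
    if (is_var(term)) {
      v <- var_name(term)
      if (!v %in% names(sol)) return(rep(NA_real_, nrow(sol)))
      suppressWarnings(as.numeric(readable_key(sol[[v]])))
    } else {
      rep(suppressWarnings(as.numeric(term$text)), nrow(sol))
    }
  }
  res <- NULL
  for (k in seq_along(f$comps)) {
    cmp <- f$comps[[k]]
    lhs <- comp_val(cmp$lhs)
    rhs <- comp_val(cmp$rhs)
    ok <- switch(cmp$op,
                 ">" = lhs > rhs, "<" = lhs < rhs,
                 ">=" = lhs >= rhs, "<=" = lhs <= rhs,
                 "=" = lhs == rhs, "!=" = lhs != rhs)
    ok[is.na(ok)] <- FALSE
    res <- if (is.null(res)) ok
           else if (f$conns[k - 1L] == "&&") res & ok
           else res | ok
  }
  sol[res, , drop = FALSE]
}

# ---- endpoint backing ------------------------------------------------------

execute_endpoint <- function(store, query) {
  full <- paste(c(sprintf("PREFIX %s: <%s>", names(store$prologue),
                          store$prologue), query), collapse = "\n")
  out <- suppressWarnings(tryCatch(
    system2("curl", c("-s", "--fail", "--max-time", "10",
                      "-H", "Accept: application/sparql-results+json",
                      "--data-urlencode", paste0("query=", full),
                      store$endpoint),
            stdout = TRUE, stderr = TRUE),
    error = function(e) structure("", status = 1L)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop(structure(class = c("chemkgqa_endpoint_error", "error", "condition"),
                   list(message = sprintf("endpoint %s unreachable",
                                          store$endpoint),
                        call = sys.call(-1))))
  }
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                               simplifyVector = FALSE)
  vars <- unlist(parsed$head$vars)
  rows <- parsed$results$bindings
  df <- as.data.frame(
    stats::setNames(lapply(vars, function(v) {
      vapply(rows, function(r) {
        if (is.null(r[[v]])) NA_character_ else r[[v]]$value
      }, character(1))
    }), vars), stringsAsFactors = FALSE, optional = TRUE)
  df
}
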