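# End-to-end question answering: preprocess, translate through a pluggable
# backend, postprocess (decode, copy-correct, relation-correct, expand) and
# execute.  Each corrective pass assumes the model detects the right text
# spans and structures but may copy or name them imperfectly.

#' Levenshtein distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming `a` into `b` (unit costs).
#'
#' @param a,b Character scalars (or vectors, recycled elementwise).
#' @return Non-negative integer(s).
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  as.integer(if (length(a) == 1L && length(b) == 1L) d[1, 1] else diag(d))
}

# Closest substring of `question` to `literal` under Levenshtein distance.
# Ties: smallest start index, then longest substring (so an exactly copied
# span beats its own prefixes — the exact-span restoration contract).
# The length window |len - nchar(literal)| <= bound is exact: any substring
# outside it is strictly worse than the incumbent bound.
closest_substring <- function(question, literal) {
  n <- nchar(question)
  if (n == 0L) return(question)
  L <- nchar(literal)
  same_len <- if (L <= n) {
    substring(question, 1:(n - L + 1L), L:(n))
  } else {
    question
  }
  bound <- min(utils::adist(literal, same_len))
  lens <- sort(max(1L, L - bound):min(n, L + bound), decreasing = TRUE)
  cands <- character()
  for (s in 1:n) {
    ls <- lens[lens <= n - s + 1L]
    if (!length(ls)) next
    cands <- c(cands, substring(question, s, s + ls - 1L))
  }
  d <- utils::adist(literal, cands)[1, ]
  cands[which.min(d)]   # enumeration order = start asc, length desc
}

#' Copy-correct grounding literals in a query
#'
#' Language models struggle to copy long repetitive surface forms (SMILES
#' strings in particular) with perfect fidelity.  Every quoted literal in
#' grounding position (VALUES blocks and literal triple objects) is
#' replaced by the substring of the input question closest to it under
#' Levenshtein distance; literals at distance 0 are unchanged.  Ties are
#' broken by smallest start index, then longest substring, so an exactly
#' copied span always beats its own prefixes.
#'
#' @param query Decoded SPARQL text.
#' @param question The input question.
#' @param max_norm_dist Optional guard: skip replacement when the
#'   normalized distance (distance / longer length) exceeds this value.
#'   Disabled (`NULL`) by default.
#' @return The corrected SPARQL text (canonically serialized).
#' @export
copy_correct <- function(query, question, max_norm_dist = NULL) {
  stopifnot(is.character(question), length(question) == 1L, nzchar(question))
  ast <- parse_sparql(query)
  fix <- function(lex) {
    best <- closest_substring(question, lex)
    if (!is.null(max_norm_dist)) {
      nd <- levenshtein(lex, best) / max(nchar(lex), nchar(best))
      if (nd > max_norm_dist) return(lex)
    }
    best
  }
  ast$where <- lapply(ast$where, function(it) {
    if (it$type == "values") {
      it$literals <- lapply(it$literals, function(l) {
        if (l$kind == "literal") term_literal(fix(l$lex), l$datatype) else l
      })
    } else if (it$type == "triple" && it$o$kind == "literal") {
      it$o <- term_literal(fix(it$o$lex), it$o$datatype)
    }
    it
  })
  serialize_sparql(ast)
}

# ---- relation correction ---------------------------------------------------

#' Character-trigram text embedder
#'
#' Deterministic, dependency-free stand-in for a sentence-embedding model:
#' texts map to L2-normalized character-trigram frequency vectors (padded,
#' lower-cased).  Any function from text to a numeric vector with
#' comparable names can be used in its place, e.g. an adapter around a
#' pretrained sentence embedder.
#'
#' @return A function `(text) -> named numeric vector`.
#' @export
trigram_embedder <- function() {
  function(text) {
    s <- paste0(" ", tolower(text), " ")
    if (nchar(s) < 3L) s <- paste0(s, "  ")
    grams <- substring(s, 1:(nchar(s) - 2L), 3:nchar(s))
    tab <- table(grams)
    v <- as.numeric(tab)
    names(v) <- names(tab)
    v / sqrt(sum(v^2))
  }
}

#' Cosine similarity of two named vectors
#'
#' @param u,v Named numeric vectors (aligned by name union).
#' @return Cosine similarity in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (!sum(u^2) || !sum(v^2)) stop("zero-vector embedding")
  keys <- union(names(u), names(v))
  uu <- stats::setNames(rep(0, length(keys)), keys)
  vv <- uu
  uu[names(u)] <- u
  vv[names(v)] <- v
  sum(uu * vv) / sqrt(sum(uu^2) * sum(vv^2))
}

# "hasBoilingPt" -> "has boiling pt"
de_camel <- function(x) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
  x <- gsub("([A-Z]+)([A-Z][a-z])", "\\1 \\2", x)
  tolower(gsub("[_-]+", " ", x))
}

# predicates that are graph plumbing, never candidates for realignment
PROTECTED_PREDICATES <- c("os:value", "os:unit", "os:hasReferenceState",
                          "rdf:type", "rdfs:label")

#' Realign out-of-schema predicates to ontology relations
#'
#' Every predicate in the ontology namespace that is not a schema relation
#' is replaced by the schema relation whose embedded label is most similar
#' (cosine) to the embedded, de-camel-cased predicate local name.
#' In-schema predicates, variable predicates and structural predicates
#' (`os:value`, `os:unit`, ...) are untouched.  Ties break by relation IRI
#' order.
#'
#' @param query Decoded SPARQL text.
#' @param schema An `ontology_schema`.
#' @param embedder A text-to-vector function; defaults to
#'   [trigram_embedder()].
#' @return The corrected SPARQL text (canonically serialized).
#' @export
relation_correct <- function(query, schema, embedder = trigram_embedder()) {
  stopifnot(inherits(schema, "ontology_schema"))
  if (!nrow(schema$relations)) stop("schema defines no relations")
  ast <- parse_sparql(query)
  rels <- schema$relations[order(schema$relations$iri), , drop = FALSE]
  rel_vecs <- lapply(rels$label, embedder)
  known <- vapply(rels$iri, pname_of, character(1),
                  prefixes = schema$prefixes)
  os_pre <- names(schema$prefixes)[schema$prefixes ==
                                     schema$prefixes[["os"]]][1]
  realign <- function(pred) {
    sims <- vapply(rel_vecs, cosine_similarity,
                   numeric(1), u = embedder(de_camel(local_name(pred))))
    known[which.max(sims)]   # ties: first in IRI order
  }
  fix_items <- function(items) {
    lapply(items, function(it) {
      if (it$type == "optional") {
        it$items <- fix_items(it$items)
      } else if (it$type == "triple" && it$p$kind == "pname" &&
                 startsWith(it$p$text, paste0(os_pre, ":")) &&
                 !it$p$text %in% PROTECTED_PREDICATES &&
                 !it$p$text %in% known) {
        it$p <- term_pname(realign(it$p$text))
      }
      it
    })
  }
  ast$where <- fix_items(ast$where)
  serialize_sparql(ast)
}

# ---- triple-pattern expansion ----------------------------------------------

#' Expand a minimal query with human-readable answer patterns
#'
#' Adds IUPAC-name retrieval for the species variable and, for each
#' numeric property variable, unit patterns plus an OPTIONAL
#' reference-state block (value, unit, label).  New variables are appended
#' to the SELECT clause in pattern order; FILTER clauses are preserved.
#' The operation is idempotent: patterns already present are not added
#' again.
#'
#' @param query Decoded SPARQL text.
#' @param schema An `ontology_schema` (identifies numeric relations).
#' @return The expanded SPARQL text.
#' @export
expand_triples <- function(query, schema) {
  stopifnot(inherits(schema, "ontology_schema"))
  ast <- parse_sparql(query)
  triples <- ast_triples(ast)
  numeric_pn <- vapply(
    schema$relations$iri[schema$relations$numeric], pname_of, character(1),
    prefixes = schema$prefixes)
  schema_pn <- vapply(schema$relations$iri, pname_of, character(1),
                      prefixes = schema$prefixes)

  # species variable: subject of a schema-relation triple (or of the
  # variable-predicate identifier pattern)
  sp_var <- NULL
  for (tr in triples) {
    if (is_var(tr$s) &&
        ((tr$p$kind == "pname" && tr$p$text %in% schema_pn) ||
         is_var(tr$p))) {
      sp_var <- tr$s$text
      break
    }
  }
  if (is.null(sp_var)) stop("cannot identify the species variable")

  has_triple <- function(p_text, s_text = NULL) {
    any(vapply(ast_triples(ast), function(tr) {
      tr$p$kind == "pname" && tr$p$text == p_text &&
        (is.null(s_text) || tr$s$text == s_text)
    }, logical(1)))
  }
  mk <- function(s, p, o) {
    list(type = "triple", s = term_var(s), p = term_pname(p), o = term_var(o))
  }
  new_select <- character()

  # IUPAC-name block, inserted before the first concrete-predicate triple
  # about the species
  if (!has_triple("os:hasIUPACName", sp_var)) {
    block <- list(mk(sp_var, "os:hasIUPACName", "?IUPACNameIRI"),
                  mk("?IUPACNameIRI", "os:value", "?IUPACNameValue"))
    pos <- Position(function(it) {
      it$type == "triple" && identical(it$s$text, sp_var) && !is_var(it$p)
    }, ast$where, nomatch = length(ast$where) + 1L)
    ast$where <- append(ast$where, block, after = pos - 1L)
    new_select <- c(new_select, "?IUPACNameValue")
  }

  # unit + optional reference state for each numeric property node
  prop_vars <- list()
  for (it in ast$where) {
    if (it$type == "triple" && it$p$kind == "pname" &&
        it$p$text %in% numeric_pn && is_var(it$o)) {
      prop_vars[[length(prop_vars) + 1L]] <- it$o$text
    }
  }
  first <- TRUE
  for (pv in unique(unlist(prop_vars))) {
    if (has_triple("os:unit", pv)) {
      first <- FALSE
      next
    }
    stem <- if (first) "" else sub("IRI$", "", sub("^\\?", "", pv))
    first <- FALSE
    u_iri <- sprintf("?%sUnitIRI", stem)
    u_val <- sprintf("?%sUnitValue", stem)
    r_iri <- sprintf("?%sRefStateIRI", stem)
    r_val <- sprintf("?%sRefStateValue", stem)
    ru_iri <- sprintf("?%sRefStateUnitIRI", stem)
    ru_val <- sprintf("?%sRefStateUnitValue", stem)
    unit_block <- list(mk(pv, "os:unit", u_iri),
                       mk(u_iri, "rdfs:label", u_val))
    opt_block <- list(type = "optional", items = list(
      mk(pv, "os:hasReferenceState", r_iri),
      mk(r_iri, "os:value", r_val),
      mk(r_iri, "os:unit", ru_iri),
      mk(ru_iri, "rdfs:label", ru_val)))
    # place the unit patterns right after the property's os:value triple
    pos <- Position(function(it) {
      it$type == "triple" && identical(it$s$text, pv) &&
        it$p$kind == "pname" && it$p$text == "os:value"
    }, ast$where, nomatch = length(ast$where))
    ast$where <- append(ast$where, c(unit_block, list(opt_block)),
                        after = pos)
    new_select <- c(new_select, u_val, r_val, ru_val)
  }

  # new variables: IUPAC name right after the species variable when it is
  # selected (else in front), unit/reference-state variables at the end
  vars <- ast$vars
  if ("?IUPACNameValue" %in% new_select) {
    at <- match(sp_var, vars)
    vars <- if (!is.na(at)) append(vars, "?IUPACNameValue", after = at)
            else c("?IUPACNameValue", vars)
    new_select <- setdiff(new_select, "?IUPACNameValue")
  }
  ast$vars <- c(vars, new_select)
  serialize_sparql(ast)
}

# ---- backends and the pipeline ---------------------------------------------

backend_translate <- function(backend, text) {
  if (inherits(backend, "translation_backend")) backend$translate(text)
  else backend(text)
}

#' Pipeline configuration
#'
#' @param prompt Instruction prompt prepended to the preprocessed question.
#' @param lexicon Unit lexicon for [convert_units()].
#' @param copy,relation,expand Enable the respective postprocessing passes.
#' @param embedder Embedder for [relation_correct()].
#' @param max_norm_dist Guard for [copy_correct()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(prompt = TRANSLATE_PROMPT,
                            lexicon = default_unit_lexicon(),
                            copy = TRUE, relation = TRUE, expand = TRUE,
                            embedder = trigram_embedder(),
                            max_norm_dist = NULL) {
  structure(list(prompt = prompt, lexicon = lexicon, copy = copy,
                 relation = relation, expand = expand, embedder = embedder,
                 max_norm_dist = max_norm_dist),
            class = "pipeline_config")
}

#' Run the full question-answering pipeline
#'
#' Stages: unit conversion, prompt prepending, backend translation,
#' decoding, copy correction, relation correction, triple-pattern
#' expansion, execution.  Every stage's output is recorded even when a
#' later stage fails; the first failing stage is named in `$error`.
#'
#' @param question Natural-language question.
#' @param backend A `translation_backend` or a function
#'   `(prompted text) -> encoded query`.
#' @param schema,kg Ontology schema and store.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` with fields question, preprocessed,
#'   predicted_encoded, decoded, copy_corrected, relation_corrected,
#'   expanded, result_table, timings and error.
#' @export
run_pipeline <- function(question, backend, schema, kg,
                         config = pipeline_config()) {
  res <- list(question = question, preprocessed = NULL,
              predicted_encoded = NULL, decoded = NULL,
              copy_corrected = NULL, relation_corrected = NULL,
              expanded = NULL, result_table = NULL,
              timings = numeric(), error = NULL)
  stage <- function(name, fn) {
    if (!is.null(res$error)) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      res$error <<- list(stage = name, message = conditionMessage(e))
      NULL
    })
    res$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  res$preprocessed <- stage("preprocess", function()
    convert_units(question, config$lexicon))
  prompted <- stage("prompt", function()
    prepend_prompt(res$preprocessed, config$prompt))
  res$predicted_encoded <- stage("translate", function()
    backend_translate(backend, prompted))
  res$decoded <- stage("decode", function()
    decode_sparql(res$predicted_encoded))
  res$copy_corrected <- stage("copy_correct", function() {
    if (config$copy) copy_correct(res$decoded, res$preprocessed$text,
                                  config$max_norm_dist)
    else res$decoded
  })
  res$relation_corrected <- stage("relation_correct", function() {
    if (config$relation) relation_correct(res$copy_corrected, schema,
                                          config$embedder)
    else res$copy_corrected
  })
  res$expanded <- stage("expand", function() {
    if (config$expand) expand_triples(res$relation_corrected, schema)
    else res$relation_corrected
  })
  res$result_table <- stage("execute", function()
    execute_select(kg, res$expanded))
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("question:", x$question, "\n")
  if (!is.null(x$error)) {
    cat(sprintf("FAILED at stage %s: %s\n", x$error$stage, x$error$message))
  } else {
    cat(sprintf("result rows: %d; stages [ms]: %s\n",
                nrow(x$result_table),
                paste(sprintf("%s=%.1f", names(x$timings),
                              1000 * unlist(x$timings)), collapse = " ")))
  }
  invisible(x)
}

#' Rule-based template backend
#'
#' A small deterministic backend translating single-relation lookup
#' questions ("what is the <relation label> of <entity>?", and the
#' imperative and keyword variants) into encoded queries by matching
#' relation labels.  Useful as a dependency-free baseline; anything it
#' cannot parse is an error.
#'
#' @param schema An `ontology_schema`.
#' @param prompt Instruction prompt to strip.
#' @return A `translation_backend`.
#' @export
rules_backend <- function(schema, prompt = TRANSLATE_PROMPT) {
  rels <- schema$relations
  translate <- function(text) {
    q <- sub(prompt, "", text, fixed = TRUE)
    m <- regmatches(q, regexec(
      "^(?:what (?:is|are) the |tell me about the )?(.+?) of (.+?)[?.]?$", q))[[1]]
    if (length(m) < 3L) stop("rules backend cannot parse question")
    hit <- which(vapply(rels$surface_forms, function(sf)
      tolower(m[2]) %in% tolower(sf), logical(1)))
    if (!length(hit)) stop(sprintf("unknown relation phrase %s", dQuote(m[2])))
    base <- rel_base(rels$iri[hit[1]])
    kind <- edge_kind(schema, rels[hit[1], ])
    sparql <- paste(c(sprintf("SELECT ?%sValue", base), "WHERE {",
                      strsplit(build_species_grounding(m[3]), "\n")[[1]],
                      property_block(base, pname_of(rels$iri[hit[1]],
                                                    schema$prefixes),
                                     value_predicate(kind)),
                      "}"), collapse = "\n")
    encode_sparql(sparql)
  }
  structure(list(translate = translate, name = "rules", precision = "full"),
            class = "translation_backend")
}

#' Fine-tuning passthrough configuration
#'
#' Hyperparameters handed to an external sequence-to-sequence fine-tuning
#' adapter; the package performs no training itself.
#'
#' @param learning_rate,adam_epsilon,batch_size,epochs Optimizer settings.
#' @param prompt Instruction prompt used during training and inference.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 2e-4, adam_epsilon = 1e-6,
                            batch_size = 32L, epochs = 3L,
                            prompt = TRANSLATE_PROMPT) {
  stopifnot(learning_rate > 0, adam_epsilon > 0, batch_size > 0, epochs > 0)
  structure(list(learning_rate = learning_rate, adam_epsilon = adam_epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), prompt = prompt),
            class = "training_config")
}
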