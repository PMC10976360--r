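# Self-contained OntoSpecies-like fixture generator: an ontology of
# chemical species with identifier subtypes, numeric properties carrying
# value + unit + optional reference state, chemical classes and uses, plus
# matching instance data.  Everything is deterministic under the config
# seed, so other modules are testable without downloads or trained models.

#' Configuration for the synthetic fixture generator
#'
#' @param n_species Number of species instances (>= 1).
#' @param properties List of numeric property descriptors: lists with
#'   `name` (CamelCase class stem), `label`, `min`, `max`, `unit`,
#'   `ref_prob` (probability of a reference-state node) and `integer`.
#' @param classes Chemical-class labels.
#' @param uses Use-annotation labels.
#' @param smiles Motif parameters for SMILES-like identifier strings:
#'   `min_repeats`, `max_repeats`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_species = 30L,
                           properties = default_fixture_properties(),
                           classes = c("alcohol", "aromatic compound",
                                       "alkane", "ketone", "ester", "amine",
                                       "carboxylic acid", "ether"),
                           uses = c("solvent", "nonpolar solvent", "fuel",
                                    "reagent", "dye", "refrigerant",
                                    "preservative", "anesthetic"),
                           smiles = list(min_repeats = 2L, max_repeats = 4L),
                           seed = 20240301L) {
  stopifnot(n_species >= 1L, length(properties) >= 1L)
  for (p in properties) {
    if (p$max <= p$min) stop(sprintf("degenerate range for %s", p$name))
  }
  structure(list(n_species = as.integer(n_species), properties = properties,
                 classes = classes, uses = uses, smiles = smiles,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

default_fixture_properties <- function() {
  list(
    list(name = "BoilingPoint", label = "boiling point", min = 184, max = 630,
         unit = "K", ref_prob = 0.5, integer = FALSE),
    list(name = "MeltingPoint", label = "melting point", min = 90, max = 500,
         unit = "K", ref_prob = 0.5, integer = FALSE),
    list(name = "MolecularWeight", label = "molecular weight", min = 16,
         max = 500, unit = "g / mol", ref_prob = 0, integer = FALSE),
    list(name = "Density", label = "density", min = 500, max = 2200,
         unit = "kg / m^3", ref_prob = 0.5, integer = FALSE),
    list(name = "OpticalRotation", label = "optical rotation", min = -120,
         max = 120, unit = "deg", ref_prob = 0, integer = FALSE),
    list(name = "Charge", label = "charge", min = -2, max = 2,
         unit = "e", ref_prob = 0, integer = TRUE))
}

#' Generate the synthetic ontology and knowledge graph
#'
#' Every species gets three identifiers (an IUPAC-like name, a SMILES-like
#' string built from repeated motifs, and a molecular formula), every
#' numeric property with value + unit and (with probability `ref_prob`) a
#' reference-state node, at least one chemical class and at least one use.
#' The output parses under [load_schema()] and loads into [kg_store()].
#'
#' @param config A [fixture_config()].
#' @return A `fixture_kg`: list with `ontology` (Turtle text), `instances`
#'   (Turtle text), `tables` (plain data frames backing brute-force test
#'   oracles) and `config`.
#' @export
generate_kg <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    ontology <- fixture_ontology(config)
    inst <- fixture_instances(config)
    structure(list(ontology = ontology, instances = inst$text,
                   tables = inst$tables, config = config),
              class = "fixture_kg")
  })
}

#' Write fixture ontology and instances to Turtle files
#'
#' @param fx A `fixture_kg` from [generate_kg()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two file paths.
#' @export
write_fixtures <- function(fx, dir) {
  stopifnot(inherits(fx, "fixture_kg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ontology = file.path(dir, "ontology.ttl"),
             instances = file.path(dir, "instances.ttl"))
  writeLines(fx$ontology, paths[["ontology"]], useBytes = TRUE)
  writeLines(fx$instances, paths[["instances"]], useBytes = TRUE)
  paths
}

fixture_ontology <- function(config) {
  l <- c(
    "@prefix os: <http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "@prefix skos: <http://www.w3.org/2004/02/skos/core#> .",
    "",
    'os:Species a owl:Class ; rdfs:label "species" .',
    'os:Identifier a owl:Class ; rdfs:label "identifier" .',
    'os:IUPACName a owl:Class ; rdfs:subClassOf os:Identifier ; rdfs:label "IUPAC name" .',
    'os:SMILES a owl:Class ; rdfs:subClassOf os:Identifier ; rdfs:label "SMILES" .',
    'os:MolecularFormula a owl:Class ; rdfs:subClassOf os:Identifier ; rdfs:label "molecular formula" .',
    'os:Use a owl:Class ; rdfs:label "use" .',
    'os:ChemicalClass a owl:Class ; rdfs:label "chemical class" .',
    'os:Unit a owl:Class ; rdfs:label "unit" .',
    'os:ReferenceState a owl:Class ; rdfs:label "reference state" .')
  for (p in config$properties) {
    # numeric ranges carry a typed os:value exemplar, the cue load_schema
    # uses to set the numeric flag on the incoming relation
    exemplar <- if (p$integer) '"0"^^xsd:integer' else '"0.0"^^xsd:decimal'
    l <- c(l,
           sprintf('os:%s a owl:Class ; rdfs:label "%s" ; os:value %s .',
                   p$name, p$label, exemplar))
  }
  l <- c(l, "",
    'os:hasIUPACName a owl:ObjectProperty ; rdfs:label "IUPAC name" ; rdfs:domain os:Species ; rdfs:range os:IUPACName .',
    'os:hasSMILES a owl:ObjectProperty ; rdfs:label "SMILES" ; rdfs:domain os:Species ; rdfs:range os:SMILES .',
    'os:hasMolecularFormula a owl:ObjectProperty ; rdfs:label "molecular formula" ; rdfs:domain os:Species ; rdfs:range os:MolecularFormula .',
    'os:hasUse a owl:ObjectProperty ; rdfs:label "use" ; rdfs:domain os:Species ; rdfs:range os:Use .',
    'os:hasChemicalClass a owl:ObjectProperty ; rdfs:label "chemical class" ; rdfs:domain os:Species ; rdfs:range os:ChemicalClass .')
  for (p in config$properties) {
    l <- c(l, sprintf(
      'os:has%s a owl:ObjectProperty ; rdfs:label "%s" ; rdfs:domain os:Species ; rdfs:range os:%s .',
      p$name, p$label, p$name))
  }
  paste(l, collapse = "\n")
}

# IUPAC-like systematic names assembled from standard morphemes
iupac_pool <- function(n) {
  prefixes <- c("", "2-methyl", "3-methyl", "2-ethyl", "2,2-dimethyl",
                "4-chloro", "3-bromo", "2-amino")
  stems <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct",
             "non", "dec")
  infixes <- c("an", "en")
  suffixes <- c("e", "-1-ol", "-2-ol", "-2-one", "al", "-1-amine",
                "oic acid", "-1-thiol")
  out <- character()
  while (length(out) < n) {
    nm <- paste0(sample(prefixes, 1L), sample(stems, 1L),
                 sample(infixes, 1L), sample(suffixes, 1L))
    if (!nm %in% out) out <- c(out, nm)
  }
  out
}

# SMILES-like strings: balanced parentheses, paired ring digits, long
# repeated motifs (the pattern copy correction must handle)
smiles_like <- function(cfg) {
  atoms <- c("C", "C", "C", "O", "N")
  frag <- function(depth) {
    k <- sample(2:4, 1L)
    parts <- character()
    for (j in seq_len(k)) {
      parts <- c(parts, sample(atoms, 1L))
      if (depth > 0L && stats::runif(1) < 0.5) {
        parts <- c(parts, "(", frag(depth - 1L), ")")
      }
    }
    paste(parts, collapse = "")
  }
  motif <- frag(2L)
  r <- sample(cfg$min_repeats:cfg$max_repeats, 1L)
  paste0("CC1", strrep(paste0("C(", motif, ")"), r), "O1")
}

molecular_formula <- function() {
  c_n <- sample(1:12, 1L)
  h_n <- sample(2:26, 1L)
  extra <- sample(c("", "O", "O2", "N", "NO"), 1L)
  paste0("C", c_n, "H", h_n, extra)
}

fixture_instances <- function(config) {
  n <- config$n_species
  names_ <- iupac_pool(n)
  lit <- function(x) paste0('"', escape_literal(x), '"')
  l <- c("@prefix os: <http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#> .",
         "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
         "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
         "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
         "")
  units <- unique(c(vapply(config$properties, `[[`, character(1), "unit"), "Pa"))
  unit_iri <- function(u) paste0("os:Unit_", gsub("[^A-Za-z0-9]", "", u))
  for (u in units) {
    l <- c(l, sprintf("%s a os:Unit ; rdfs:label %s .", unit_iri(u), lit(u)))
  }
  for (k in seq_along(config$uses)) {
    l <- c(l, sprintf("os:Use_%d a os:Use ; rdfs:label %s .",
                      k, lit(config$uses[k])))
  }
  for (k in seq_along(config$classes)) {
    l <- c(l, sprintf("os:ChemicalClass_%d a os:ChemicalClass ; rdfs:label %s .",
                      k, lit(config$classes[k])))
  }
  species_tab <- data.frame(iri = character(), iupac = character(),
                            smiles = character(), formula = character())
  prop_tab <- data.frame(species = character(), relation = character(),
                         value = numeric(), unit = character(),
                         ref_value = numeric(), ref_unit = character())
  use_tab <- data.frame(species = character(), use = character())
  class_tab <- data.frame(species = character(), class = character())

  for (i in seq_len(n)) {
    sp <- sprintf("os:Species_%d", i)
    sm <- smiles_like(config$smiles)
    fo <- molecular_formula()
    l <- c(l, "",
           sprintf("%s a os:Species .", sp),
           sprintf("%s os:hasIUPACName os:IUPACName_%d .", sp, i),
           sprintf("os:IUPACName_%d a os:IUPACName ; os:value %s .", i,
                   lit(names_[i])),
           sprintf("%s os:hasSMILES os:SMILES_%d .", sp, i),
           sprintf("os:SMILES_%d a os:SMILES ; os:value %s .", i, lit(sm)),
           sprintf("%s os:hasMolecularFormula os:MolecularFormula_%d .", sp, i),
           sprintf("os:MolecularFormula_%d a os:MolecularFormula ; os:value %s .",
                   i, lit(fo)))
    species_tab <- rbind(species_tab,
                         data.frame(iri = sp, iupac = names_[i], smiles = sm,
                                    formula = fo))
    for (p in config$properties) {
      v <- if (p$integer) sample(seq(p$min, p$max), 1L)
           else round(stats::runif(1, p$min, p$max), 2)
      node <- sprintf("os:%s_%d", p$name, i)
      dt <- if (p$integer) "xsd:integer" else "xsd:decimal"
      l <- c(l,
             sprintf("%s os:has%s %s .", sp, p$name, node),
             sprintf('%s a os:%s ; os:value "%s"^^%s ; os:unit %s .',
                     node, p$name, format_quantity(v), dt, unit_iri(p$unit)))
      ref_v <- NA_real_
      if (stats::runif(1) < p$ref_prob) {
        ref_v <- round(stats::runif(1, 8e4, 1.1e5))
        ref <- sprintf("os:RefState_%s_%d", p$name, i)
        l <- c(l,
               sprintf("%s os:hasReferenceState %s .", node, ref),
               sprintf('%s a os:ReferenceState ; os:value "%s"^^xsd:decimal ; os:unit %s .',
                       ref, format_quantity(ref_v), unit_iri("Pa")))
      }
      prop_tab <- rbind(prop_tab, data.frame(
        species = sp, relation = paste0("has", p$name), value = v,
        unit = p$unit, ref_value = ref_v,
        ref_unit = if (is.na(ref_v)) NA_character_ else "Pa"))
    }
    for (k in sample(seq_along(config$uses), sample(1:3, 1L))) {
      l <- c(l, sprintf("%s os:hasUse os:Use_%d .", sp, k))
      use_tab <- rbind(use_tab, data.frame(species = sp,
                                           use = config$uses[k]))
    }
    for (k in sample(seq_along(config$classes), sample(1:2, 1L))) {
      l <- c(l, sprintf("%s os:hasChemicalClass os:ChemicalClass_%d .", sp, k))
      class_tab <- rbind(class_tab, data.frame(species = sp,
                                               class = config$classes[k]))
    }
  }
  list(text = paste(l, collapse = "\n"),
       tables = list(species = species_tab, properties = prop_tab,
                     uses = use_tab, classes = class_tab))
}

# ---- gold dataset and backend ---------------------------------------------

#' Build a gold dataset and question-to-query map
#'
#' Wraps [assemble_dataset()] for test harnesses: returns the dataset plus
#' an injective map from question text to gold encoded query, suitable for
#' [gold_backend()].
#'
#' @param schema,kg Schema and store loaded from [generate_kg()] output.
#' @param n Total number of examples.
#' @param seed Integer seed.
#' @return List with `dataset` (a `qa_dataset`) and `gold_map` (named
#'   character vector question -> encoded query).
#' @export
make_gold_dataset <- function(schema, kg, n = 50L, seed = 1L) {
  holdout <- max(1L, n %/% 10L)
  sizes <- c(train = n - 2L * holdout, dev = holdout, test = holdout)
  ds <- assemble_dataset(schema, kg, sizes, seed = seed)
  qs <- vapply(ds$examples, `[[`, character(1), "question")
  enc <- vapply(ds$examples, `[[`, character(1), "encoded_query")
  stopifnot(!anyDuplicated(qs))
  list(dataset = ds, gold_map = stats::setNames(enc, qs))
}

#' Gold translation backend
#'
#' Answers each known question with its own gold encoded query — the
#' identity backend used to validate the pipeline end to end.
#'
#' @param gold_map Named character vector question -> encoded query.
#' @param prompt The instruction prompt the pipeline prepends.
#' @return A `translation_backend`.
#' @export
gold_backend <- function(gold_map, prompt = TRANSLATE_PROMPT) {
  translate <- function(text) {
    q <- sub(prompt, "", text, fixed = TRUE)
    if (!q %in% names(gold_map)) {
      stop(sprintf("gold backend has no entry for %s", dQuote(q)))
    }
    unname(gold_map[[q]])
  }
  structure(list(translate = translate, name = "gold", precision = "full"),
            class = "translation_backend")
}

# ---- controlled corruptions ------------------------------------------------

CORRUPTION_MODES <- c("typo_in_literal", "relation_synonym", "structure_drop",
                      "function_flip", "brace_break")

#' Specification of a controlled corruption
#'
#' Each mode exercises one corrective or diagnostic path: `typo_in_literal`
#' (copy correction), `relation_synonym` (relation correction / relation
#' error), `structure_drop` (query-structure error), `function_flip`
#' (function error), `brace_break` (syntax error).
#'
#' @param mode One of the five modes.
#' @param magnitude Number of single-character edits (typo mode).
#' @param seed Optional integer seed.
#' @return A `corruption_spec`.
#' @export
corruption_spec <- function(mode, magnitude = 1L, seed = NULL) {
  mode <- match.arg(mode, CORRUPTION_MODES)
  stopifnot(magnitude >= 1L)
  structure(list(mode = mode, magnitude = as.integer(magnitude), seed = seed),
            class = "corruption_spec")
}

#' Corrupt a gold query in a controlled way
#'
#' @param example A QA example (needs `encoded_query`), or an encoded query
#'   string.
#' @param spec A [corruption_spec()].
#' @return The corrupted predicted query, in encoded form.
#' @export
corrupt <- function(example, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  enc <- if (is.character(example)) example else example$encoded_query
  run <- function() corrupt_impl(enc, spec)
  if (!is.null(spec$seed)) with_seed(spec$seed, run()) else run()
}

corrupt_impl <- function(enc, spec) {
  if (spec$mode == "brace_break") {
    pos <- gregexpr("&rcub;", enc, fixed = TRUE)[[1]]
    if (pos[1] == -1L) stop("brace_break inapplicable: no closing brace")
    last <- pos[length(pos)]
    return(paste0(substr(enc, 1, last - 1L),
                  substr(enc, last + 6L, nchar(enc))))
  }
  ast <- parse_sparql(decode_sparql(enc))
  ast <- switch(spec$mode,
    typo_in_literal = corrupt_literal(ast, spec$magnitude),
    relation_synonym = corrupt_relation(ast),
    structure_drop = corrupt_structure(ast),
    function_flip = corrupt_function(ast))
  encode_sparql(serialize_sparql(ast))
}

random_edit <- function(s) {
  alphabet <- c(LETTERS, letters, 0:9)
  op <- sample(c("sub", "ins", if (nchar(s) > 1L) "del"), 1L)
  i <- sample.int(nchar(s), 1L)
  switch(op,
    sub = {
      ch <- sample(setdiff(alphabet, substr(s, i, i)), 1L)
      paste0(substr(s, 1, i - 1L), ch, substr(s, i + 1L, nchar(s)))
    },
    ins = paste0(substr(s, 1, i), sample(alphabet, 1L),
                 substr(s, i + 1L, nchar(s))),
    del = paste0(substr(s, 1, i - 1L), substr(s, i + 1L, nchar(s))))
}

corrupt_literal <- function(ast, magnitude) {
  vi <- which(vapply(ast$where, function(it) it$type == "values", logical(1)))
  if (!length(vi)) stop("typo_in_literal inapplicable: no grounding literal")
  vi <- vi[sample.int(length(vi), 1L)]
  li <- sample.int(length(ast$where[[vi]]$literals), 1L)
  lex <- ast$where[[vi]]$literals[[li]]$lex
  for (k in seq_len(magnitude)) lex <- random_edit(lex)
  ast$where[[vi]]$literals[[li]] <- term_literal(lex)
  ast
}

# out-of-schema variants via common abbreviation patterns
SYNONYM_MAP <- c(Point = "Pt", Weight = "Wt", Molecular = "Mol",
                 Rotation = "Rot", Chemical = "Chem", Formula = "Form",
                 Reference = "Ref")

corrupt_relation <- function(ast) {
  idx <- which(vapply(ast$where, function(it) {
    it$type == "triple" && it$p$kind == "pname" &&
      grepl("^os:has", it$p$text) && it$p$text != "os:hasReferenceState"
  }, logical(1)))
  if (!length(idx)) stop("relation_synonym inapplicable: no schema predicate")
  i <- idx[sample.int(length(idx), 1L)]
  pred <- ast$where[[i]]$p$text
  variant <- pred
  for (k in names(SYNONYM_MAP)) {
    if (grepl(k, variant, fixed = TRUE)) {
      variant <- sub(k, SYNONYM_MAP[[k]], variant, fixed = TRUE)
      break
    }
  }
  if (variant == pred) variant <- paste0(pred, "Of")
  ast$where[[i]]$p <- term_pname(variant)
  ast
}

corrupt_structure <- function(ast) {
  idx <- which(vapply(ast$where, function(it) it$type == "triple", logical(1)))
  if (length(idx) < 2L) stop("structure_drop inapplicable: too few triples")
  ast$where[[idx[sample.int(length(idx), 1L)]]] <- NULL
  ast
}

corrupt_function <- function(ast) {
  fi <- which(vapply(ast$where, function(it) it$type == "filter", logical(1)))
  if (!length(fi)) stop("function_flip inapplicable: no filter")
  fi <- fi[sample.int(length(fi), 1L)]
  f <- ast$where[[fi]]
  f$comps <- lapply(f$comps, function(cmp) {
    cmp$op <- chartr("<>", "><", cmp$op)
    cmp
  })
  f$conns <- ifelse(f$conns == "&&", "||", "&&")
  ast$where[[fi]] <- f
  ast
}
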