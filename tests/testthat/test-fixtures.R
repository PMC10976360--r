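test_that("the fixture KG has the configured shape", {
  fx <- generate_kg(fixture_config(n_species = 10L, seed = 3L))
  expect_equal(nrow(fx$tables$species), 10L)
  kg <- kg_store(instances = fx$instances)
  schema <- load_schema(fx$ontology)
  species <- chemkgqa:::kg_species(kg, schema)
  expect_length(species, 10L)
  # every species carries >= 2 identifiers, >= 1 class, >= 1 use
  for (sp in species) {
    ids <- chemkgqa:::kg_identifier_values(kg, schema, sp)
    expect_gte(length(ids), 2L)
  }
  expect_true(all(table(fx$tables$classes$species) >= 1))
  expect_true(all(table(fx$tables$uses$species) >= 1))
})

test_that("generation is deterministic and loads losslessly", {
  cfg <- fixture_config(n_species = 6L, seed = 12L)
  f1 <- generate_kg(cfg)
  f2 <- generate_kg(cfg)
  expect_identical(f1$ontology, f2$ontology)
  expect_identical(f1$instances, f2$instances)
  t1 <- chemkgqa:::parse_turtle(f1$instances)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(f1, dir)
  t2 <- chemkgqa:::parse_turtle(paths[["instances"]])
  expect_equal(nrow(t1$triples), nrow(t2$triples))
  expect_identical(t1$triples, t2$triples)
})

test_that("every numeric property node follows the value/unit/ref-state pattern", {
  fe <- test_fixture()
  tab <- fe$fx$tables$properties
  for (i in seq_len(nrow(tab))) {
    q <- paste(c(
      "SELECT ?v ?u", "WHERE {",
      sprintf("%s os:%s ?p .", tab$species[i], tab$relation[i]),
      "?p os:value ?v .",
      "?p os:unit ?uIRI .",
      "?uIRI rdfs:label ?u .", "}"), collapse = "\n")
    res <- execute_select(fe$kg, q)
    expect_gte(nrow(res), 1L)
    expect_true(chemkgqa:::format_quantity(tab$value[i]) %in% res$v)
    expect_true(tab$unit[i] %in% res$u)
    if (!is.na(tab$ref_value[i])) {
      qr <- paste(c(
        "SELECT ?rv ?ru", "WHERE {",
        sprintf("%s os:%s ?p .", tab$species[i], tab$relation[i]),
        "?p os:hasReferenceState ?r .",
        "?r os:value ?rv .",
        "?r os:unit ?ruIRI .",
        "?ruIRI rdfs:label ?ru .", "}"), collapse = "\n")
      rr <- execute_select(fe$kg, qr)
      expect_gte(nrow(rr), 1L)
      expect_true(tab$ref_unit[i] %in% rr$ru)
    }
  }
})

test_that("SMILES-like identifiers are balanced and repetitive", {
  fe <- test_fixture()
  for (sm in fe$fx$tables$species$smiles) {
    open <- lengths(regmatches(sm, gregexpr("(", sm, fixed = TRUE)))
    close <- lengths(regmatches(sm, gregexpr(")", sm, fixed = TRUE)))
    expect_equal(open, close)
    expect_gte(nchar(sm), 15L)
  }
})

test_that("gold datasets are injective and fully executable", {
  fe <- test_fixture()
  gd <- test_gold()
  expect_equal(anyDuplicated(names(gd$gold_map)), 0L)
  for (enc in gd$gold_map[1:15]) {
    res <- execute_select(fe$kg, decode_sparql(enc))
    expect_gte(nrow(res), 1L)
  }
})

test_that("corruption modes honor their contracts", {
  gd <- test_gold()
  enc <- gd$dataset$examples[[
    which(vapply(gd$dataset$examples, function(e)
      length(e$metadata$functions) > 0 &&
        grepl("VALUES", decode_sparql(e$encoded_query), fixed = TRUE),
      logical(1)))[1]]]$encoded_query
  # typo: exactly one edit at magnitude 1
  bad <- corrupt(enc, corruption_spec("typo_in_literal", magnitude = 1L,
                                      seed = 5L))
  lits <- function(x) {
    ast <- chemkgqa:::parse_sparql(decode_sparql(x))
    unlist(lapply(Filter(function(it) it$type == "values", ast$where),
                  function(v) vapply(v$literals, `[[`, character(1), "lex")))
  }
  d <- mapply(levenshtein, lits(enc), lits(bad))
  expect_equal(sum(d), 1)
  # magnitude-3 typos apply three edits (distance bounded by 3)
  bad3 <- corrupt(enc, corruption_spec("typo_in_literal", magnitude = 3L,
                                       seed = 5L))
  expect_lte(sum(mapply(levenshtein, lits(enc), lits(bad3))), 3)
  # broken braces no longer parse
  broken <- corrupt(enc, corruption_spec("brace_break"))
  expect_error(chemkgqa:::parse_sparql(decode_sparql(broken)))
  # flipped functions change the comparison structure
  flipped <- corrupt(enc, corruption_spec("function_flip", seed = 5L))
  expect_false(identical(flipped, enc))
  # inapplicable modes are errors
  no_filter <- "SELECT var_x WHERE &lcub; var_x os:value var_v . &rcub;"
  expect_error(corrupt(no_filter, corruption_spec("function_flip")),
               "inapplicable")
  expect_error(corrupt(no_filter, corruption_spec("typo_in_literal")),
               "inapplicable")
})

test_that("each corruption mode lands in its intended error category", {
  gd <- test_gold()
  with_filter <- Filter(function(e) length(e$metadata$functions) > 0,
                        gd$dataset$examples)
  intended <- c(relation_synonym = "relation",
                structure_drop = "query_structure",
                function_flip = "function",
                brace_break = "syntax")
  set.seed(31)
  for (mode in names(intended)) {
    for (k in 1:20) {
      e <- with_filter[[sample.int(length(with_filter), 1L)]]
      bad <- corrupt(e$encoded_query, corruption_spec(mode))
      expect_identical(classify_errors(e$encoded_query, bad),
                       unname(intended[mode]))
    }
  }
  # typo_in_literal is the copy-correction trigger: the pass snaps every
  # corrupted literal to its closest question substring (which is the
  # original span unless the typo accidentally matches another span)
  with_values <- Filter(function(e)
    grepl("VALUES", decode_sparql(e$encoded_query), fixed = TRUE),
    gd$dataset$examples)
  grounding_lits <- function(sparql_text) {
    ast <- chemkgqa:::parse_sparql(sparql_text)
    unlist(lapply(Filter(function(it) it$type == "values", ast$where),
                  function(v) vapply(v$literals, `[[`, character(1), "lex")))
  }
  for (k in 1:20) {
    e <- with_values[[sample.int(length(with_values), 1L)]]
    bad <- decode_sparql(corrupt(e$encoded_query,
                                 corruption_spec("typo_in_literal")))
    fixed <- copy_correct(bad, e$question)
    expected <- vapply(grounding_lits(bad), brute_closest_substring,
                       character(1), question = e$question)
    expect_identical(grounding_lits(fixed), unname(expected))
  }
})
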