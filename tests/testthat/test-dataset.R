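test_that("subgraph sampling respects the out-degree contract", {
  fe <- test_fixture()
  set.seed(1)
  sub <- sample_subgraph(fe$schema, 2)
  expect_s3_class(sub, "schema_subgraph")
  expect_equal(nrow(sub$edges), 2L)
  expect_equal(anyDuplicated(sub$edges$iri), 0L)
  expect_error(sample_subgraph(fe$schema, 0), "\\[1, 3\\]")
  expect_error(sample_subgraph(fe$schema, 4), "\\[1, 3\\]")
  # fixed seed reproduces the draw
  a <- withr::with_seed(42, sample_subgraph(fe$schema, 3))
  b <- withr::with_seed(42, sample_subgraph(fe$schema, 3))
  expect_identical(a$edges$iri, b$edges$iri)
  tiny <- load_schema('
@prefix os: <http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
os:Species a owl:Class . os:Identifier a owl:Class . os:Use a owl:Class .
os:hasUse a owl:ObjectProperty ; rdfs:label "use" ;
  rdfs:domain os:Species ; rdfs:range os:Use .')
  expect_error(sample_subgraph(tiny, 2), "only 1 relations")
})

test_that("comparative filters realize the five operators", {
  f <- comparative_filter("higher", 373, variable = "BoilingPointValue")
  expect_identical(build_filter(f), "FILTER ( ?BoilingPointValue > 373 )")
  expect_identical(build_filter(comparative_filter("lower", 250, variable = "v")),
                   "FILTER ( ?v < 250 )")
  expect_equal(filter_bounds(comparative_filter("around", 100)), c(90, 110))
  # user bounds may arrive unordered; the query normalizes them
  f_in <- comparative_filter("inside", 373, 350, variable = "v")
  expect_identical(build_filter(f_in), "FILTER ( ?v > 350 && ?v < 373 )")
  f_out <- comparative_filter("outside", 400, 300, variable = "v")
  expect_identical(build_filter(f_out), "FILTER ( ?v < 300 || ?v > 400 )")
  expect_error(comparative_filter("around", -5), "a > 0")
  expect_error(comparative_filter("inside", 1), "both bounds")
  expect_error(comparative_filter("higher", 1, 2), "single threshold")
})

test_that("species grounding emits the VALUES + identifier-matching block", {
  g <- build_species_grounding("benzene")
  expect_match(g, 'VALUES (?species) { ("benzene") }', fixed = TRUE)
  expect_match(g, "?SpeciesIRI ?hasIdentifier ?IdentifierIRI .", fixed = TRUE)
  expect_match(g, "?IdentifierIRI os:value ?species .", fixed = TRUE)
  expect_match(build_species_grounding('4"-methyl'), '4\\"-methyl',
               fixed = TRUE)
  expect_error(build_species_grounding(""), "non-empty")
})

test_that("grounded queries parse, execute and answer on the fixture KG", {
  fe <- test_fixture()
  set.seed(21)
  for (intent in c("property_lookup", "species_search", "class_property")) {
    for (rep in 1:5) {
      q <- random_canonical_query(intent)
      expect_identical(q$intent, intent)
      res <- execute_select(fe$kg, q$sparql)
      expect_gte(nrow(res), 1L)   # groundings are drawn from the KG
      # grounded surfaces appear verbatim in question and VALUES block
      question <- verbalize(q, sample(c("interrogative", "imperative",
                                        "keyword"), 1L))
      for (gr in q$groundings) {
        expect_match(question, gr$text, fixed = TRUE)
        expect_match(q$sparql, sprintf('("%s")',
                                       chemkgqa:::escape_literal(gr$text)),
                     fixed = TRUE)
      }
    }
  }
  # incompatible intent is an error
  repeat {
    sub <- sample_subgraph(fe$schema, 1)
    if (!any(chemkgqa:::subgraph_kinds(sub) == "class")) break
  }
  expect_error(ground_query(sub, "class_property", fe$kg), "incompatible")
})

test_that("species searches agree with a brute-force scan of the fixture", {
  fe <- test_fixture()
  set.seed(33)
  for (rep in 1:20) {
    q <- random_canonical_query("species_search")
    got <- execute_select(fe$kg, q$sparql)
    got <- sort(unique(chemkgqa:::local_name(got$SpeciesIRI)))
    expect_identical(got, brute_species_search(q, fe$fx$tables))
  }
})

test_that("verbalization templates realize the three forms", {
  vl <- chemkgqa:::verbalize_lookup
  expect_identical(vl("charge", "benzene", "interrogative"),
                   "what is the charge of benzene?")
  expect_identical(vl("charge", "benzene", "imperative"),
                   "tell me about the charge of benzene.")
  expect_identical(vl("charge", "benzene", "keyword"), "charge of benzene")
  expect_identical(vl(c("boiling point", "charge"), "benzene",
                      "interrogative"),
                   "what are the boiling point and charge of benzene?")
  f <- comparative_filter("around", 300, variable = "v")
  expect_identical(chemkgqa:::filter_phrase(f), "around 300")
  f2 <- comparative_filter("inside", 373, 350, variable = "v")
  expect_identical(chemkgqa:::filter_phrase(f2),
                   "inside the range between 373 and 350")
})

test_that("paraphrases preserve entity mentions and keyword forms are skipped", {
  accepted <- collect_paraphrases(
    "what is the boiling point of water?", entities = "water",
    provider = function(text, n) c("at what temperature does water boil?",
                                   "when does H2O boil?"), n = 5)
  expect_identical(accepted, "at what temperature does water boil?")
  calls <- 0L
  counting <- function(text, n) {
    calls <<- calls + 1L
    character()
  }
  out <- collect_paraphrases("charge of benzene", "benzene", counting,
                             form = "keyword")
  expect_identical(out, character())
  expect_identical(calls, 0L)
  # provider failure leaves the canonical question usable
  expect_identical(
    collect_paraphrases("what is the charge of benzene?", "benzene",
                        provider = function(text, n) stop("API down")),
    character())
})

test_that("assembled datasets have disjoint splits and correct statistics", {
  gd <- test_gold()
  ds <- gd$dataset
  expect_length(ds$examples, 50L)
  qs <- vapply(ds$examples, `[[`, character(1), "question")
  splits <- vapply(ds$examples, `[[`, character(1), "split")
  expect_equal(anyDuplicated(qs), 0L)
  expect_equal(sum(splits == "dev"), 5L)
  expect_equal(sum(splits == "test"), 5L)
  # the final question always comes from the canonical + paraphrase pool
  for (e in ds$examples) {
    expect_true(e$question %in% c(e$canonical_question, e$paraphrases))
    expect_silent(parse_ok <- decode_sparql(e$encoded_query))
  }
  s <- ds$stats
  expect_equal(sum(s$pct_by_relation_count), 100, tolerance = 1e-8)
  expect_true(all(s$pct_function >= 0 & s$pct_function <= 100))
  # function occurrence re-counted by scanning the stored queries' FILTER
  # clauses (around is the chained comparison whose bounds sit at the
  # 0.9a/1.1a ratio)
  ops_of_query <- function(encoded) {
    ast <- chemkgqa:::parse_sparql(decode_sparql(encoded))
    vapply(chemkgqa:::ast_filters(ast), function(f) {
      ops <- vapply(f$comps, `[[`, character(1), "op")
      if (length(ops) == 1L) return(if (ops == ">") "higher" else "lower")
      if (any(f$conns == "||")) return("outside")
      vals <- sort(vapply(f$comps, function(cmp)
        as.numeric(cmp$rhs$text), numeric(1)))
      if (abs(vals[2] / vals[1] - 11 / 9) < 1e-9) "around" else "inside"
    }, character(1))
  }
  recount <- vapply(c("higher", "lower", "inside", "outside", "around"),
                    function(op) {
                      100 * mean(vapply(ds$examples, function(e)
                        op %in% ops_of_query(e$encoded_query), logical(1)))
                    }, numeric(1))
  expect_equal(unname(s$pct_function), unname(recount))
})

test_that("hand-built statistics arithmetic", {
  ex <- list(
    list(metadata = list(n_relations = 1, functions = character())),
    list(metadata = list(n_relations = 2, functions = "around")))
  s <- dataset_stats(ex)
  expect_equal(unname(s$pct_by_relation_count), c(50, 50, 0))
  expect_equal(unname(s$pct_function["around"]), 50)
  expect_equal(s$size, 2L)
})

test_that("generation is reproducible and round-trips through JSON Lines", {
  fe <- test_fixture()
  sizes <- c(train = 8, dev = 2, test = 2)
  d1 <- assemble_dataset(fe$schema, fe$kg, sizes, seed = 99)
  d2 <- assemble_dataset(fe$schema, fe$kg, sizes, seed = 99)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_qa_dataset(d1, p1)
  write_qa_dataset(d2, p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-identical dataset
  back <- read_qa_dataset(p1)
  expect_equal(length(back$examples), 12L)
  expect_identical(back$examples[[1]]$question, d1$examples[[1]]$question)
  expect_identical(back$stats, d1$stats)
})
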