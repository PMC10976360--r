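MINI_ONT <- '
@prefix os: <http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
os:Species a owl:Class ; rdfs:label "species" .
os:Identifier a owl:Class .
os:BoilingPoint a owl:Class ; rdfs:label "boiling point" ; os:value "0.0"^^xsd:decimal .
os:hasBoilingPoint a owl:ObjectProperty ; rdfs:label "boiling point" ;
  rdfs:domain os:Species ; rdfs:range os:BoilingPoint .
os:hasIUPACName a owl:ObjectProperty ; rdfs:label "IUPAC name" ;
  rdfs:domain os:Species ; rdfs:range os:Identifier .
'

test_that("load_schema extracts classes, relations and numeric flags", {
  schema <- load_schema(MINI_ONT)
  expect_equal(nrow(schema$classes), 3L)
  expect_equal(nrow(schema$relations), 2L)
  expect_true(schema$relations$numeric[grepl("hasBoilingPoint",
                                             schema$relations$iri)])
  expect_false(schema$relations$numeric[grepl("hasIUPACName",
                                              schema$relations$iri)])
  expect_match(schema$species_class, "Species$")
})

test_that("load_schema is idempotent and validates its input", {
  fe <- test_fixture()
  s1 <- load_schema(fe$fx$ontology)
  s2 <- load_schema(fe$fx$ontology)
  expect_identical(s1, s2)
  expect_error(load_schema(""), "no classes found")
  bad <- paste0(MINI_ONT, '
os:hasGhost a owl:ObjectProperty ; rdfs:label "ghost" ;
  rdfs:domain os:Phantom ; rdfs:range os:Species .')
  expect_error(load_schema(bad), "hasGhost")
})

test_that("relations_from filters by domain in stable IRI order", {
  fe <- test_fixture()
  rels <- relations_from(fe$schema, fe$schema$species_class)
  expect_true(all(rels$domain == fe$schema$species_class))
  expect_identical(rels$iri, sort(rels$iri))
  expect_identical(rels, relations_from(fe$schema, fe$schema$species_class))
  expect_error(relations_from(fe$schema, "os:NoSuchClass"), "not defined")
  # a class with no outgoing relations yields an empty set
  use_cls <- fe$schema$classes$iri[grepl("#Use$", fe$schema$classes$iri)]
  expect_equal(nrow(relations_from(fe$schema, use_cls)), 0L)
})

test_that("execute_select answers, returns empty tables, flags bad syntax", {
  fe <- test_fixture()
  name1 <- fe$fx$tables$species$iupac[1]
  q <- paste(c("SELECT ?SpeciesIRI", "WHERE {",
               build_species_grounding(name1), "}"), collapse = "\n")
  res <- execute_select(fe$kg, q)
  expect_gte(nrow(res), 1L)
  # a species absent from the KG: valid query, empty response, no error
  q_absent <- paste(c("SELECT ?SpeciesIRI", "WHERE {",
                      build_species_grounding("unobtainium dioxide"), "}"),
                    collapse = "\n")
  expect_equal(nrow(execute_select(fe$kg, q_absent)), 0L)
  expect_error(execute_select(fe$kg, "SELECT ?x WHERE { ?x os:value ?y ."),
               class = "chemkgqa_syntax_error")
  # repeated execution neither mutates the store nor reorders results
  before <- fe$kg$triples
  expect_identical(execute_select(fe$kg, q), res)
  expect_identical(fe$kg$triples, before)
})

test_that("executor agrees with an independent SPARQL engine (rdflib)", {
  fx <- generate_kg(fixture_config(n_species = 6L, seed = 77L))
  schema <- load_schema(fx$ontology)
  kg <- kg_store(instances = fx$instances)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(fx, dir)
  queries <- list(
    paste(c("SELECT ?IUPACNameValue ?BoilingPointValue", "WHERE {",
            build_species_grounding(fx$tables$species$iupac[2]),
            "?SpeciesIRI os:hasIUPACName ?IUPACNameIRI .",
            "?IUPACNameIRI os:value ?IUPACNameValue .",
            "?SpeciesIRI os:hasBoilingPoint ?BoilingPointIRI .",
            "?BoilingPointIRI os:value ?BoilingPointValue .", "}"),
          collapse = "\n"),
    paste(c("SELECT ?SpeciesIRI", "WHERE {",
            "?SpeciesIRI os:hasMeltingPoint ?MeltingPointIRI .",
            "?MeltingPointIRI os:value ?MeltingPointValue .",
            "FILTER ( ?MeltingPointValue > 200 && ?MeltingPointValue < 400 )",
            "}"), collapse = "\n"),
    paste(c("SELECT ?UseValue", "WHERE {",
            sprintf('VALUES (?ChemicalClassValue) { ("%s") }',
                    fx$tables$classes$class[1]),
            "?SpeciesIRI os:hasChemicalClass ?ChemicalClassIRI .",
            "?ChemicalClassIRI rdfs:label ?ChemicalClassValue .",
            "?SpeciesIRI os:hasUse ?UseIRI .",
            "?UseIRI rdfs:label ?UseValue .", "}"), collapse = "\n"))
  for (q in queries) {
    ours <- execute_select(kg, q)
    ours_rows <- lapply(seq_len(nrow(ours)), function(i)
      unname(as.character(ours[i, ])))
    theirs <- rdflib_select(paths[["instances"]], q)
    theirs <- lapply(theirs, function(r) unname(unlist(r)))
    expect_setequal(ours_rows, theirs)
  }
})

test_that("an unreachable endpoint is reported as such", {
  store <- kg_store(endpoint = "http://127.0.0.1:9/sparql")
  expect_error(execute_select(store, "SELECT ?x WHERE { ?x os:value ?y . }"),
               class = "chemkgqa_endpoint_error")
})
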