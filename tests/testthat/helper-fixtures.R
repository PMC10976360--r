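# Shared fixture build (cached per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

test_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- generate_kg(fixture_config(seed = 101L))
    .fixture_cache$schema <- load_schema(.fixture_cache$fx$ontology)
    .fixture_cache$kg <- kg_store(instances = .fixture_cache$fx$instances)
  }
  .fixture_cache
}

test_gold <- function(n = 50L, seed = 7L) {
  key <- paste0("gold_", n, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    fe <- test_fixture()
    .fixture_cache[[key]] <- make_gold_dataset(fe$schema, fe$kg, n = n,
                                               seed = seed)
  }
  .fixture_cache[[key]]
}

# generate one grounded canonical query of a compatible intent
random_canonical_query <- function(intent = NULL) {
  fe <- test_fixture()
  repeat {
    it <- intent %||% sample(c("property_lookup", "species_search",
                               "class_property"), 1L)
    od <- if (it == "class_property") sample(2:3, 1L) else sample(1:3, 1L)
    sub <- sample_subgraph(fe$schema, od)
    if (intent_compatible(sub, it)) {
      return(ground_query(sub, it, fe$kg))
    }
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
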