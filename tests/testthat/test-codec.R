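test_that("encoding substitutes variable prefixes and structural characters", {
  enc <- encode_sparql("SELECT ?SpeciesIRI ?BoilingPointValue")
  expect_identical(enc, "SELECT var_SpeciesIRI var_BoilingPointValue")
  expect_identical(encode_sparql("WHERE {"), "WHERE &lcub;")
  expect_identical(encode_sparql("FILTER (?BoilingPointValue > 373)"),
                   "FILTER (var_BoilingPointValue &gt; 373)")
  # whitespace preserved byte for byte
  expect_identical(encode_sparql("a   ?b\n\tc"), "a   var_b\n\tc")
})

test_that("literal content is protected from variable substitution", {
  q <- 'SELECT ?x WHERE { VALUES (?species) { ("is it ?x or {that}?") } }'
  enc <- encode_sparql(q)
  expect_match(enc, '"is it ?x or &lcub;that&rcub;?"', fixed = TRUE)
  expect_false(grepl("var_x or", enc))
  expect_identical(decode_sparql(enc), q)
})

test_that("reserved sequences in the input are rejected", {
  for (bad in c("SELECT var_x", "a &lt; b", "x &lcub; y")) {
    expect_error(encode_sparql(bad), "reserved sequence")
  }
})

test_that("decoding inverts the variable prefix and flags dangling entities", {
  expect_identical(decode_sparql("var_x os:value var_v"), "?x os:value ?v")
  expect_error(decode_sparql("WHERE &lcub"), class = "chemkgqa_decode_error")
  expect_error(decode_sparql("FILTER ( var_x &gt 3 )"),
               class = "chemkgqa_decode_error")
  # a bare ampersand is not an entity fragment
  expect_identical(decode_sparql('VALUES (var_x) { ("AT&T") }'),
                   'VALUES (?x) { ("AT&T") }')
})

test_that("decode(encode(q)) is the identity on generated queries", {
  set.seed(11)
  for (i in 1:100) {
    q <- random_canonical_query()$sparql
    expect_identical(decode_sparql(encode_sparql(q)), q)
  }
})
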