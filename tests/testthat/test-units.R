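test_that("temperature mentions convert to kelvin", {
  p <- convert_units("boiling point between 100 and 120 °C")
  expect_identical(p$text, "boiling point between 373.15 and 393.15 K")
  expect_identical(p$conversions$dimension, "temperature")
  expect_identical(convert_units("melting point above 212 °F")$text,
                   "melting point above 373.15 K")
  expect_identical(convert_units("boiling point around 25 degrees Celsius")$text,
                   "boiling point around 298.15 K")
})

test_that("pressure mentions convert to pascal", {
  expect_identical(convert_units("reference state of 1 atm")$text,
                   "reference state of 101325 Pa")
  expect_identical(convert_units("at 101.325 kPa")$text, "at 101325 Pa")
})

test_that("text without quantities or with unknown units passes through", {
  p <- convert_units("charge of benzene")
  expect_identical(p$text, "charge of benzene")
  expect_equal(nrow(p$conversions), 0L)
  expect_identical(convert_units("a span of 5 furlongs")$text,
                   "a span of 5 furlongs")
  # SI mentions stay untouched
  expect_identical(convert_units("stays at 300 K")$text, "stays at 300 K")
})

test_that("every conversion's converted span occurs in the rewritten text", {
  qs <- c("between 100 and 120 °C", "above 2 bar and below 760 mmHg",
          "melting point of -40 °C")
  for (qn in qs) {
    p <- convert_units(qn)
    for (i in seq_len(nrow(p$conversions))) {
      expect_match(p$text, p$conversions$converted[i], fixed = TRUE)
    }
  }
})

test_that("conversions invert through the affine map to 1e-9 relative tolerance", {
  lex <- default_unit_lexicon()
  set.seed(5)
  for (i in seq_len(nrow(lex))) {
    row <- lex[i, ]
    vals <- round(stats::runif(20, -50, 400), 3)
    si <- vals * row$scale + row$offset
    back <- (si - row$offset) / row$scale
    expect_equal(back, vals, tolerance = 1e-9)
  }
  # through the formatted text as the pipeline emits it
  p <- convert_units("melting point above 212 °F")
  shown <- as.numeric(sub(".*above ([0-9.]+) K", "\\1", p$text))
  f_row <- lex[lex$surface == "°F", ]
  expect_equal((shown - f_row$offset) / f_row$scale, 212, tolerance = 1e-9)
})

test_that("the instruction prompt is prepended verbatim", {
  expect_identical(prepend_prompt("charge of benzene"),
                   "translate to SPARQL: charge of benzene")
  expect_identical(prepend_prompt(""), "translate to SPARQL: ")
  expect_identical(prepend_prompt(convert_units("charge of benzene")),
                   "translate to SPARQL: charge of benzene")
})
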