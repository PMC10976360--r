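test_that("exact-match accuracy is a word-level identity score", {
  pairs <- data.frame(gold = c("SELECT var_x WHERE", "a b c"),
                      predicted = c("SELECT  var_x  WHERE", "a b d"))
  expect_equal(exact_match_accuracy(pairs), 50)   # whitespace runs collapse
  pairs$predicted <- pairs$gold
  expect_equal(exact_match_accuracy(pairs), 100)
  pairs$predicted[1] <- paste(pairs$gold[1], "extra")
  expect_equal(exact_match_accuracy(pairs), 50)
  expect_error(exact_match_accuracy(data.frame(gold = character(),
                                               predicted = character())),
               "no evaluation pairs")
})

test_that("corpus BLEU is 100 at identity and ~0 on disjoint corpora", {
  gd <- test_gold()
  enc <- vapply(gd$dataset$examples, `[[`, character(1), "encoded_query")
  ident <- data.frame(gold = enc, predicted = enc)
  expect_equal(corpus_bleu(ident), 100)
  expect_equal(exact_match_accuracy(ident), 100)
  disjoint <- data.frame(gold = "a b c d e", predicted = "v w x y z")
  expect_lt(corpus_bleu(disjoint), 0.5)
})

test_that("corpus BLEU matches a hand-computed toy-corpus value", {
  pairs <- data.frame(
    gold = c("the cat sat on the mat", "dogs bark loudly at night"),
    predicted = c("the cat sat on the mat", "dogs bark loudly at midnight"))
  # hand counts: p1 = 10/11, p2 = 8/9, p3 = 6/7, p4 = 4/5; lengths equal
  expected <- 100 * (10 / 11 * 8 / 9 * 6 / 7 * 4 / 5)^(1 / 4)
  expect_equal(corpus_bleu(pairs), expected, tolerance = 1e-4)
})

test_that("corpus BLEU is invariant under pair reordering", {
  gd <- test_gold()
  enc <- vapply(gd$dataset$examples[1:10], `[[`, character(1),
                "encoded_query")
  pred <- enc
  pred[1] <- corrupt(enc[1], corruption_spec("function_flip", seed = 3))
  pairs <- data.frame(gold = enc, predicted = pred)
  set.seed(2)
  perm <- sample(nrow(pairs))
  expect_equal(corpus_bleu(pairs), corpus_bleu(pairs[perm, ]))
})

test_that("error classification distinguishes the four aspects", {
  gd <- test_gold()
  enc <- gd$dataset$examples[[
    which(vapply(gd$dataset$examples, function(e)
      length(e$metadata$functions) > 0, logical(1)))[1]]]$encoded_query
  expect_identical(classify_errors(enc, enc), character())
  expect_identical(
    classify_errors(enc, corrupt(enc, corruption_spec("brace_break"))),
    "syntax")
  expect_identical(
    classify_errors(enc, corrupt(enc, corruption_spec("relation_synonym",
                                                      seed = 4))),
    "relation")
  expect_identical(
    classify_errors(enc, corrupt(enc, corruption_spec("function_flip",
                                                      seed = 4))),
    "function")
  expect_identical(
    classify_errors(enc, corrupt(enc, corruption_spec("structure_drop",
                                                      seed = 4))),
    "query_structure")
})

test_that("unparseable gold is a distinct dataset fault", {
  expect_error(classify_errors("SELECT var_x WHERE &lcub", "whatever"),
               "dataset fault")
})

test_that("empty category set occurs exactly at exact match", {
  gd <- test_gold()
  set.seed(6)
  for (e in gd$dataset$examples[1:15]) {
    enc <- e$encoded_query
    expect_identical(length(classify_errors(enc, enc)) == 0L, TRUE)
    mode <- sample(c("relation_synonym", "function_flip", "structure_drop",
                     "brace_break"), 1L)
    bad <- tryCatch(corrupt(enc, corruption_spec(mode)),
                    error = function(e2) NULL)
    if (is.null(bad)) next
    cats <- classify_errors(enc, bad)
    expect_gt(length(cats), 0L)
    expect_lt(exact_match_accuracy(data.frame(gold = enc, predicted = bad)),
              100)
  }
})

test_that("evaluation reports aggregate the three metrics over n examples", {
  gd <- test_gold()
  enc <- vapply(gd$dataset$examples[1:10], `[[`, character(1),
                "encoded_query")
  pred <- enc
  pred[3] <- corrupt(enc[3], corruption_spec("relation_synonym", seed = 2))
  rep <- evaluate_translations(data.frame(gold = enc, predicted = pred))
  expect_equal(rep$accuracy_pct, 90)
  expect_equal(rep$n, 10L)
  expect_equal(unname(rep$error_breakdown["relation"]), 10)
  expect_equal(unname(rep$error_breakdown["syntax"]), 0)
  expect_lt(rep$corpus_score, 100)
  # identity corpus: perfect scores, empty breakdown
  rep0 <- evaluate_translations(data.frame(gold = enc, predicted = enc))
  expect_equal(rep0$accuracy_pct, 100)
  expect_equal(rep0$corpus_score, 100)
  expect_true(all(rep0$error_breakdown == 0))
})
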