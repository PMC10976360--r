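# Dataset assembly: sample subgraphs, ground, verbalize, paraphrase, pick
# the final question from the pool, split into train/dev/test and compute
# corpus statistics.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Assemble a question/SPARQL dataset
#'
#' Runs the full generation pipeline: for each example an intent and an
#' out-degree are sampled, a compatible schema subgraph is drawn and
#' grounded against the KG, the query is verbalized in one of three forms,
#' paraphrases are collected, and the final question is sampled uniformly
#' from the pool of the canonical question and its accepted paraphrases.
#' Question texts are unique across the dataset, so splits are disjoint.
#'
#' @param schema An `ontology_schema`.
#' @param kg An in-memory `kg_store`.
#' @param sizes Named integer vector `c(train = , dev = , test = )`.
#' @param config Optional list: `paraphraser` (provider function, default
#'   [rule_paraphraser()]), `n_paraphrases` (default 5).
#' @param seed Integer seed; the same seed yields a byte-identical dataset.
#' @return A `qa_dataset`: list with `examples` (list of QA examples:
#'   question, encoded_query, canonical_question, paraphrases, split,
#'   metadata) and `stats` (see [dataset_stats()]).
#' @export
assemble_dataset <- function(schema, kg, sizes, config = list(), seed = 1L) {
  stopifnot(all(c("train", "dev", "test") %in% names(sizes)),
            all(sizes > 0))
  provider <- config$paraphraser %||% rule_paraphraser()
  n_para <- config$n_paraphrases %||% 5L
  total <- sum(sizes)

  examples <- with_seed(seed, {
    out <- vector("list", total)
    seen <- character()
    attempts <- 0L
    k <- 0L
    while (k < total) {
      attempts <- attempts + 1L
      if (attempts > 60L * total) {
        stop("could not generate enough unique questions; enlarge the KG")
      }
      intent <- sample(QUERY_INTENTS, 1L)
      od <- if (intent == "class_property") sample(2:3, 1L) else sample(1:3, 1L)
      sub <- NULL
      for (try in 1:100) {
        cand <- sample_subgraph(schema, od)
        if (intent_compatible(cand, intent)) {
          sub <- cand
          break
        }
      }
      if (is.null(sub)) next
      q <- tryCatch(ground_query(sub, intent, kg), error = function(e) NULL)
      if (is.null(q)) next
      form <- sample(VERBALIZATION_FORMS, 1L)
      canonical <- verbalize(q, form)
      entities <- vapply(q$groundings, `[[`, character(1), "text")
      paras <- collect_paraphrases(canonical, entities, provider,
                                   n = n_para, form = form)
      question <- sample(c(canonical, paras), 1L)
      if (question %in% seen) next
      seen <- c(seen, question)
      k <- k + 1L
      out[[k]] <- list(
        question = question,
        encoded_query = encode_sparql(q$sparql),
        canonical_question = canonical,
        paraphrases = paras,
        split = NA_character_,
        metadata = list(intent = q$intent,
                        n_relations = q$n_relations,
                        functions = vapply(q$filters, `[[`, character(1), "op")))
    }
    out
  })

  split <- rep(c("train", "dev", "test"),
               times = c(sizes[["train"]], sizes[["dev"]], sizes[["test"]]))
  for (i in seq_along(examples)) examples[[i]]$split <- split[i]
  structure(list(examples = examples, stats = dataset_stats(examples)),
            class = "qa_dataset")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Dataset statistics
#'
#' Size, percentage of examples by relation count (1 to 3) and percentage
#' of examples in which each comparative operator occurs.
#'
#' @param examples List of QA examples (as in a `qa_dataset`).
#' @return List with `size`, `pct_by_relation_count` (named over "1","2",
#'   "3", summing to 100) and `pct_function` (named over the five
#'   operators).
#' @export
dataset_stats <- function(examples) {
  if (inherits(examples, "qa_dataset")) examples <- examples$examples
  n <- length(examples)
  stopifnot(n > 0L)
  nrel <- vapply(examples, function(e) e$metadata$n_relations, numeric(1))
  pct_rel <- vapply(1:3, function(k) 100 * mean(nrel == k), numeric(1))
  names(pct_rel) <- as.character(1:3)
  pct_fun <- vapply(FILTER_OPS, function(op) {
    100 * mean(vapply(examples, function(e)
      op %in% e$metadata$functions, logical(1)))
  }, numeric(1))
  list(size = n, pct_by_relation_count = pct_rel, pct_function = pct_fun)
}

#' @export
print.qa_dataset <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<qa_dataset> %d examples\n", s$size))
  cat("relations:", paste(sprintf("%s: %.1f%%", names(s$pct_by_relation_count),
                                  s$pct_by_relation_count), collapse = ", "), "\n")
  cat("functions:", paste(sprintf("%s: %.1f%%", names(s$pct_function),
                                  s$pct_function), collapse = ", "), "\n")
  invisible(x)
}

#' Write a dataset as JSON Lines
#'
#' One JSON object per example with fields question, encoded_query,
#' canonical_question, paraphrases, split and metadata.
#'
#' @param ds A `qa_dataset` (or its `examples` list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qa_dataset <- function(ds, path) {
  examples <- if (inherits(ds, "qa_dataset")) ds$examples else ds
  lines <- vapply(examples, function(e) {
    e$paraphrases <- as.list(e$paraphrases)
    e$metadata$functions <- as.list(e$metadata$functions)
    jsonlite::toJSON(e, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines dataset written by [write_qa_dataset()]
#'
#' @param path Input file path.
#' @return A `qa_dataset`.
#' @export
read_qa_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  examples <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    e$paraphrases <- as.character(unlist(e$paraphrases))
    e$metadata$functions <- as.character(unlist(e$metadata$functions))
    e
  })
  structure(list(examples = examples, stats = dataset_stats(examples)),
            class = "qa_dataset")
}
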