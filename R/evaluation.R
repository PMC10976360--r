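# Translation-quality evaluation: exact-match accuracy, corpus-level BLEU
# and a four-way error taxonomy (syntax, query structure, relation,
# function).  Both metrics tokenize the encoded query strings on
# whitespace — the representation the model actually emits.

normalize_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("gold", "predicted") %in% names(pairs)))
    if (!"question" %in% names(pairs)) pairs$question <- rep("", nrow(pairs))
    return(pairs)
  }
  stopifnot(is.list(pairs), length(pairs) > 0L)
  data.frame(
    gold = vapply(pairs, `[[`, character(1), "gold"),
    predicted = vapply(pairs, `[[`, character(1), "predicted"),
    question = vapply(pairs, function(p) p$question %||% "", character(1)),
    stringsAsFactors = FALSE)
}

ws_tokens <- function(x) strsplit(trimws(x), "[[:space:]]+")[[1]]

#' Exact-match translation accuracy
#'
#' A prediction scores 1 iff its whitespace-token sequence is identical to
#' the gold reference (case-sensitive; runs of whitespace collapse).
#'
#' @param pairs Data frame (or list of lists) with columns/fields `gold`
#'   and `predicted` (encoded query text).
#' @return Mean score as a percentage in [0, 100].
#' @export
exact_match_accuracy <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  if (!nrow(pairs)) stop("no evaluation pairs given")
  hits <- vapply(seq_len(nrow(pairs)), function(i)
    identical(ws_tokens(pairs$gold[i]), ws_tokens(pairs$predicted[i])),
    logical(1))
  100 * mean(hits)
}

#' Corpus-level BLEU score
#'
#' Corpus BLEU with n-gram orders 1-4, brevity penalty and exponential
#' smoothing for zero higher-order counts, on whitespace-tokenized encoded
#' queries, scaled to 0-100.
#'
#' @inheritParams exact_match_accuracy
#' @param max_order Highest n-gram order (default 4).
#' @return Score in [0, 100]; 100 iff the corpora are token-identical.
#' @export
corpus_bleu <- function(pairs, max_order = 4L) {
  pairs <- normalize_pairs(pairs)
  if (!nrow(pairs)) stop("no evaluation pairs given")
  matches <- total <- numeric(max_order)
  hyp_len <- ref_len <- 0
  for (i in seq_len(nrow(pairs))) {
    ref <- ws_tokens(pairs$gold[i])
    hyp <- ws_tokens(pairs$predicted[i])
    ref_len <- ref_len + length(ref)
    hyp_len <- hyp_len + length(hyp)
    for (k in seq_len(max_order)) {
      hg <- ngrams(hyp, k)
      rg <- ngrams(ref, k)
      total[k] <- total[k] + length(hg)
      if (length(hg)) {
        ht <- table(hg)
        rt <- table(rg)
        shared <- intersect(names(ht), names(rt))
        matches[k] <- matches[k] + sum(pmin(ht[shared], rt[shared]))
      }
    }
  }
  if (total[1] == 0 || matches[1] == 0) return(0)  # zero unigram precision
  smooth <- 1
  logp <- numeric(0)
  for (k in seq_len(max_order)) {
    if (total[k] == 0) next
    if (matches[k] == 0) {
      smooth <- smooth * 2
      logp <- c(logp, log(1 / (smooth * total[k])))
    } else {
      logp <- c(logp, log(matches[k] / total[k]))
    }
  }
  bp <- if (hyp_len >= ref_len) 1 else exp(1 - ref_len / hyp_len)
  100 * bp * exp(mean(logp))
}

ngrams <- function(tokens, k) {
  n <- length(tokens)
  if (n < k) return(character())
  vapply(1:(n - k + 1L), function(i)
    paste(tokens[i:(i + k - 1L)], collapse = "\x1f"), character(1))
}

# ---- error taxonomy --------------------------------------------------------

ERROR_CATEGORIES <- c("syntax", "query_structure", "relation", "function")

abstract_term <- function(term) {
  if (is_var(term)) "?" else term$text
}

# triple patterns with predicates abstracted away, as sortable strings
structure_signature <- function(ast) {
  sig <- vapply(ast_triples(ast), function(tr)
    paste(abstract_term(tr$s), "~", abstract_term(tr$o)), character(1))
  values <- Filter(function(it) it$type == "values", ast$where)
  vsig <- vapply(values, function(v)
    paste("VALUES", paste(sort(vapply(v$literals, serialize_term,
                                      character(1))), collapse = " ")),
    character(1))
  sort(c(sig, vsig, paste("arity", length(ast$vars))))
}

predicate_multiset <- function(ast) {
  sort(vapply(Filter(function(tr) !is_var(tr$p), ast_triples(ast)),
              function(tr) tr$p$text, character(1)))
}

filter_signature <- function(ast) {
  sort(vapply(ast_filters(ast), function(f) {
    ops <- vapply(f$comps, `[[`, character(1), "op")
    vals <- vapply(f$comps, function(cmp) {
      num <- Filter(function(t) !is_var(t), list(cmp$lhs, cmp$rhs))
      if (length(num)) num[[1]]$text else ""
    }, character(1))
    paste(paste(ops, vals, collapse = " "), "|",
          paste(f$conns, collapse = " "))
  }, character(1)))
}

#' Classify an incorrect prediction by aspect of the logical form
#'
#' Exact matches yield the empty set.  A prediction that fails to decode
#' or parse is a `syntax` error (no further categories assessed).
#' Otherwise: `query_structure` if the predicate-abstracted triple-pattern
#' multiset, the VALUES groundings or the SELECT arity differ; `relation`
#' if structures align but at least one predicate differs; `function` if
#' the FILTER operator types or bound structure differ.  Non-syntax
#' categories may co-occur.
#'
#' @param gold,predicted Encoded query texts.
#' @param schema Unused by the structural checks but kept in the signature
#'   for classifier variants that consult the ontology.
#' @return Character vector of categories (possibly empty).
#' @export
classify_errors <- function(gold, predicted, schema = NULL) {
  if (identical(ws_tokens(gold), ws_tokens(predicted))) return(character())
  gold_ast <- tryCatch(parse_sparql(decode_sparql(gold)),
                       error = function(e) NULL)
  if (is.null(gold_ast)) stop("gold query does not decode/parse (dataset fault)")
  pred_ast <- tryCatch(parse_sparql(decode_sparql(predicted)),
                       error = function(e) NULL)
  if (is.null(pred_ast)) return("syntax")
  out <- character()
  if (!identical(structure_signature(gold_ast),
                 structure_signature(pred_ast))) {
    out <- c(out, "query_structure")
  } else if (!identical(predicate_multiset(gold_ast),
                        predicate_multiset(pred_ast))) {
    out <- c(out, "relation")
  }
  if (!identical(filter_signature(gold_ast), filter_signature(pred_ast))) {
    out <- c(out, "function")
  }
  out
}

#' Evaluate a set of translation pairs
#'
#' @param pairs Data frame or list with `gold`, `predicted` and optionally
#'   `question`.
#' @param schema Passed to [classify_errors()].
#' @return An `eval_report`: list with `accuracy_pct`, `corpus_score`,
#'   `error_breakdown` (percent of all examples per category; categories
#'   may co-occur, so percentages need not sum to the error rate) and `n`.
#' @export
evaluate_translations <- function(pairs, schema = NULL) {
  pairs <- normalize_pairs(pairs)
  if (!nrow(pairs)) stop("no evaluation pairs given")
  cats <- lapply(seq_len(nrow(pairs)), function(i)
    classify_errors(pairs$gold[i], pairs$predicted[i], schema))
  breakdown <- vapply(ERROR_CATEGORIES, function(cat)
    100 * mean(vapply(cats, function(x) cat %in% x, logical(1))), numeric(1))
  structure(list(accuracy_pct = exact_match_accuracy(pairs),
                 corpus_score = corpus_bleu(pairs),
                 error_breakdown = breakdown,
                 n = nrow(pairs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.2f%%  corpus BLEU=%.2f\n",
              x$n, x$accuracy_pct, x$corpus_score))
  nz <- x$error_breakdown[x$error_breakdown > 0]
  if (length(nz)) {
    cat("errors:", paste(sprintf("%s: %.1f%%", names(nz), nz),
                         collapse = ", "), "\n")
  }
  invisible(x)
}
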