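# Independent oracles, implemented separately from the package code paths
# they check.

# textbook dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, integer(length(B)))
    for (j in seq_along(B)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (A[i] != B[j]))
    }
    prev <- cur
  }
  prev[length(B) + 1L]
}

# exhaustive closest-substring scan (no pruning); ties by smallest start,
# then longest substring — candidates enumerated in exactly that order
brute_closest_substring <- function(question, literal) {
  n <- nchar(question)
  cands <- character()
  for (s in 1:n) cands <- c(cands, substring(question, s, n:s))
  d <- utils::adist(literal, cands)[1, ]
  cands[which.min(d)]
}

# independent trigram-cosine nearest schema label
oracle_trigrams <- function(text) {
  s <- paste0(" ", tolower(text), " ")
  table(substring(s, seq_len(nchar(s) - 2L), seq_len(nchar(s) - 2L) + 2L))
}

oracle_nearest_label <- function(query_text, labels) {
  qt <- oracle_trigrams(query_text)
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_along(labels)) {
    lt <- oracle_trigrams(labels[i])
    shared <- intersect(names(qt), names(lt))
    num <- sum(as.numeric(qt[shared]) * as.numeric(lt[shared]))
    sim <- num / sqrt(sum(as.numeric(qt)^2) * sum(as.numeric(lt)^2))
    if (sim > best) {
      best <- sim
      best_i <- i
    }
  }
  best_i
}

# de-camel-casing mirrored independently of the package helper (acronym
# runs split before a trailing capitalized word, as documented)
oracle_decamel <- function(x) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
  x <- gsub("([A-Z]+)(?=[A-Z][a-z])", "\\1 ", x, perl = TRUE)
  tolower(x)
}

# execute a query through Python rdflib on Turtle files (independent
# SPARQL engine); returns sorted rows as a list of character vectors
rdflib_select <- function(ttl_paths, query) {
  prologue <- paste(sprintf("PREFIX %s: <%s>",
                            names(chemkgqa:::default_prefixes()),
                            chemkgqa:::default_prefixes()), collapse = "\n")
  qfile <- tempfile(fileext = ".rq")
  writeLines(paste(prologue, query, sep = "\n"), qfile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import rdflib",
    "g = rdflib.Graph()",
    "for p in sys.argv[2:]:",
    "    g.parse(p, format='turtle')",
    "q = open(sys.argv[1]).read()",
    "rows = [[str(v) if v is not None else None for v in row]",
    "        for row in g.query(q)]",
    "print(json.dumps(sorted(rows)))"), script)
  out <- system2("python", c(script, qfile, ttl_paths), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# brute-force scan of the fixture tables for a species_search query
brute_species_search <- function(q, tables) {
  conds <- q$meta$conditions
  rel_local <- vapply(q$relations, chemkgqa:::local_name, character(1))
  keep <- vapply(tables$species$iri, function(sp) {
    for (i in seq_along(conds)) {
      cond <- conds[[i]]
      ok <- switch(cond$type,
        use = any(tables$uses$species == sp & tables$uses$use == cond$surface),
        class = any(tables$classes$species == sp &
                      tables$classes$class == cond$surface),
        numeric = {
          vals <- tables$properties$value[
            tables$properties$species == sp &
              tables$properties$relation == rel_local[i]]
          length(vals) && any(chemkgqa:::filter_satisfied(cond$filter, vals))
        })
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(sub("^os:", "", tables$species$iri[keep]))
}
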