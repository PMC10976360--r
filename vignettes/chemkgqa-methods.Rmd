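---
title: "Question answering over a chemical-species knowledge graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Question answering over a chemical-species knowledge graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemkgqa)
```

## The problem

Chemical knowledge graphs in the OntoSpecies style store species with
their identifiers (IUPAC names, SMILES strings, molecular formulas),
numeric physical properties carrying a value, a unit and sometimes a
reference state, chemical-class memberships and use annotations.
Querying them requires SPARQL and schema knowledge.  A
sequence-to-sequence translator can map natural-language questions to
SPARQL, but it needs (a) training data, (b) a query representation its
tokenizer can digest, and (c) corrective postprocessing to absorb the
residual uncertainty of generation.  `chemkgqa` implements all three as
a model-agnostic framework: any function from prompted text to encoded
query can serve as the translation backend.

## Dataset generation

Generation proceeds in three steps.  First, schema subgraphs rooted at
the species class are sampled: the out-degree of the species node varies
from 1 to 3, drawn uniformly by default (the range is fixed; the
distribution over it was an open choice and is uniform because no
evidence favors any weighting).  Second, subgraphs are grounded against
instance data into one of three intents: one-hop lookups about a
grounded species, searches for species satisfying conditions, and
two-hop questions about properties of species in a chemical class.
Third, each query is verbalized and paraphrased.

Entity linking happens inside the query, by exact string matching: a
species is bound through a `VALUES` clause containing one of its
identifier surface forms, matched via a variable-predicate pattern
against the value of any identifier subtype.  Because the linking is
exact, grounding literals are drawn from the knowledge graph itself, so
every generated query has at least one answer; this mirrors grounding a
subgraph together with its instantiation.

Numeric conditions use five comparative operators: `higher` (x > a),
`lower` (x < a), `inside` (a < x < b), `outside` (x < a or x > b) and
`around`, which expands to the band from 0.9a to 1.1a and is defined
only for a > 0.  Operators are sampled uniformly per numeric qualifier.
Thresholds are anchored at an actual property value of an anchor
species, offset by at least one unit or 15 % of the value (whichever is
larger) and rounded to one decimal for readable questions — the
rounding is verified against the anchor so answerability is never lost.
For `inside`/`outside` the two bounds are presented in random order and
the query normalizes them, since users supply unordered bounds
("between 373 and 350").

Verbalization is template-based and deterministic per (intent, form,
operator): interrogative ("what is the charge of benzene?"), imperative
("tell me about the charge of benzene.") and keyword ("charge of
benzene").  Paraphrasing goes through a provider interface; the default
provider is a deterministic rule-based rewriter of sentence frames, and
a remote LLM can be plugged in instead.  Accepted paraphrases must
contain every grounded entity surface form verbatim — the automatic
counterpart of a manual semantic check, necessary because entity linking
is exact-match.  Keyword verbalizations are never paraphrased.  The
final question is sampled uniformly from the canonical question plus its
accepted paraphrases, and question texts are unique across the dataset,
which makes the train/dev/test splits disjoint by construction.

## Query encoding

Tokenizers of text-to-text models trained on natural language treat
`<`, `>`, `{`, `}` as out-of-vocabulary and strip whitespace before a
question mark, which destroys the SPARQL variable marker.  Queries are
therefore encoded before a model sees them: the four structural
characters become HTML entities (`&lt;`, `&gt;`, `&lcub;`, `&rcub;`)
and `?name` becomes `var_name`.  Variable substitution applies only
outside quoted literals (a question mark inside a SMILES string or name
is data, not syntax); the character substitutions are global with a
global inverse, which is safe because inputs containing any reserved
target sequence are rejected up front.  `decode_sparql()` is an exact
inverse; a dangling entity fragment (`&lcub` without `;`) is the
signature of malformed model output and raises a decode error rather
than propagating garbage.

## Postprocessing

**Copy correction.**  Models detect the right text spans but copy long
repetitive surface forms (SMILES strings especially) imperfectly.  Every
quoted literal in grounding position — `VALUES` rows and literal triple
objects, never IRIs, which carry no entity surface forms in this
grammar — is replaced by the substring of the input question with
minimal Levenshtein distance.  Ties break by smallest start index, then
longest substring; preferring the longest means an exactly copied span
always beats its own prefixes, which is what exact-span restoration
requires.  The search is exact: an initial bound from same-length
substrings limits candidate lengths to `len(literal) ± bound` (any
substring outside that window is strictly worse), and the surviving
candidates are scanned exhaustively.  A configurable maximum normalized
distance can veto replacements in deployments; it is disabled by
default because the generator's questions always contain the intended
span.

**Relation correction.**  Predicates in the ontology namespace that are
not schema relations are realigned to the schema relation whose embedded
label is most cosine-similar to the embedded predicate local name,
de-camel-cased first so that surface embedding is meaningful
("hasBoilingPt" → "has boiling pt").  The default embedder is an
L2-normalized character-trigram frequency vector — deterministic and
dependency-free; a pretrained sentence embedder can be swapped in
through the same interface.  In-schema predicates are never touched, and
neither are the structural predicates (`os:value`, `os:unit`,
`os:hasReferenceState`, `rdfs:label`): realignment is for hallucinated
relation names, not graph plumbing.

**Triple-pattern expansion.**  Minimal answers (an IRI, a bare number)
are not human-readable.  The expansion pass adds IUPAC-name retrieval
for the species variable and, for every numeric property variable, unit
patterns plus an `OPTIONAL` block retrieving the reference state's
value, unit and label — `OPTIONAL` because reference states are
genuinely optional in the data and their absence must not suppress the
answer.  New variables join the SELECT clause in pattern order; the pass
is idempotent by presence checks, so re-running it (or expanding a
query a model already expanded) adds nothing.

**Unit conversion.**  Input questions are rewritten to SI units before
translation, since the knowledge graph stores SI.  The lexicon ships
temperature (°C, °F, K and spelled-out variants) and pressure (atm,
bar, mmHg, kPa, Pa) as affine conversions `si = value * scale +
offset`; shared-unit ranges ("between 100 and 120 °C") convert both
numbers.  Unknown units pass through unchanged — silently breaking on
them would be worse than leaving the model to cope.  Converted numbers
print at full precision with trailing zeros trimmed (12 significant
digits, far below the 1e-9 relative tolerance the inverse map is tested
to).

## Evaluation

Exact-match accuracy scores a prediction 1 iff its whitespace-token
sequence equals the gold reference.  The corpus score is corpus-level
BLEU (orders 1–4, brevity penalty) on whitespace tokens of the encoded
strings — queries are code-like, so linguistic tokenizers would distort
the n-grams, and scoring the encoded form scores exactly what the model
emits.  Zero higher-order counts get exponential smoothing; zero
unigram overlap yields exactly 0, and token-identical corpora exactly
100.

The error taxonomy classifies each wrong prediction by aspect: `syntax`
(the decoded prediction fails to parse; nothing further is assessed),
`query_structure` (the predicate-abstracted triple-pattern multiset,
the VALUES groundings or the SELECT arity differ), `relation`
(structures align but a predicate differs) and `function` (FILTER
operator types or bound structure differ).  The non-syntax categories
are not mutually exclusive and are reported as sets; percentages in a
report are over all examples.  These operational definitions are the
package's own — only the four category names are fixed externally.

## Synthetic fixtures

The fixture generator emulates an OntoSpecies-like KG so every module is
testable without downloads or trained models: 30 species by default,
each with three identifiers, six numeric properties (boiling and
melting points, molecular weight, density, optical rotation, charge)
drawn uniformly from realistic ranges with units, reference states
attached with probability 0.5 where they make physical sense (the
pressure at which a boiling point was measured), plus 1–2 chemical
classes and 1–3 uses per species.  SMILES-like identifiers are built
from repeated motifs with balanced parentheses and paired ring digits —
syntactically plausible, not chemically valid, because copy correction
is a string problem and chemical validity is irrelevant to the tested
contract.  IUPAC-like names are assembled from standard morphemes
("2-methylbutan-1-ol").  Everything is byte-reproducible under the
config seed.

Controlled corruptions drive the negative tests: a literal typo
(exercises copy correction), an out-of-schema relation synonym
(relation correction / `relation` category), a dropped triple
(`query_structure`), a flipped comparative operator (`function`) and an
unbalanced brace (`syntax`).

What passing tests do and do not show: the fixture KG has clean,
complete, deduplicated data, one value per property, and questions that
always contain the grounded spans verbatim.  Real KGs aggregate
duplicate property values from multiple sources, carry missing
properties for rare species (the correct behavior — a valid query with
an empty answer — is tested, but sparsity is not emulated), and real
users phrase questions outside the template grammar.  Perfect scores
under the gold backend validate the plumbing, not translation quality
of any actual model.

## Numerical and engineering choices

* No R RDF or SPARQL library is available in the package's dependency
  footprint, so the Turtle reader and SELECT executor are implemented
  here, restricted to the closed grammar the generator emits (basic
  graph patterns with variables in any position, single-variable
  `VALUES`, numeric FILTER comparisons chained by `&&`/`||`,
  `OPTIONAL`).  The test suite cross-checks execution against an
  independent SPARQL engine on small fixtures.
* Queries serialize canonically (one triple per line, terminated by
  `.`); every AST-rewriting pass re-serializes, so idempotence checks
  are byte-level.
* Result tables are ordered lexicographically for determinism; SPARQL
  row order is otherwise unspecified.
* Levenshtein distances use the standard unit-cost edit distance from
  base R; the closest-substring search built on it is exact (see above).
* Dataset generation at the default scale (30 species, 50 examples)
  takes about a second; the full test suite, including 1,000-query
  codec round trips and 200 brute-force copy-correction comparisons,
  runs in under a minute on one CPU.

## Limitations

The executor covers the generator's grammar, not all of SPARQL 1.1;
feeding it hand-written queries outside that fragment raises a syntax
error rather than wrong answers.  Aggregates, property paths and
`ORDER BY` are out of scope, as are OWL reasoning and SPARQL UPDATE.
Fine-tuning and 8-bit quantization are external concerns: the package
stores passthrough hyperparameters (`training_config()`) and treats
precision as backend metadata.  Duplicate-row filtering of results is
deliberately not performed.
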