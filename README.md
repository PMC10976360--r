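# chemkgqa

Knowledge-graph question answering (KGQA) over chemical-species data:
a model-agnostic R framework for translating natural-language chemistry
questions into SPARQL, generating the question/query training data such
a translator needs, and measuring translation quality.

Chemistry knowledge graphs in the OntoSpecies style describe species
through identifier subtypes (IUPAC name, SMILES, molecular formula),
numeric properties carrying value + unit + optional reference state,
chemical-class memberships and uses.  Retrieving anything from them
requires SPARQL and schema knowledge.  `chemkgqa` wraps that gap with a
pipeline in three steps:

1. **Preprocessing** — physical quantities in the question are converted
   to SI units (`100 °C` → `373.15 K`) and the instruction prompt
   `"translate to SPARQL: "` is prepended.
2. **Translation** — a pluggable backend maps the prompted question to a
   query in a sequence-to-sequence-safe encoding: `?var` → `var_var`,
   and `<`, `>`, `{`, `}` → `&lt;`, `&gt;`, `&lcub;`, `&rcub;` (these
   characters are out-of-vocabulary for natural-language tokenizers, and
   a bare `?` prefix is mangled by whitespace stripping).  Backends are
   just functions from text to text; a gold lookup backend and a
   rule-based template backend ship with the package, and fine-tuning
   hyperparameters (`training_config()`) pass through to any external
   seq2seq adapter.
3. **Postprocessing** — the prediction is decoded, *copy-corrected*
   (every grounding literal is replaced by the substring of the question
   minimizing Levenshtein distance — models misspell long repetitive
   SMILES spans), *relation-corrected* (out-of-schema predicates are
   realigned to the ontology relation with the highest cosine similarity
   between embedded labels), *expanded* with triple patterns retrieving
   IUPAC names, units and reference states, and executed against the KG.

The dataset generator samples schema subgraphs rooted at the species
class (out-degree 1–3), grounds them against instance data so every
query has an answer, attaches one comparative operator per numeric
qualifier from {higher, lower, inside, outside, around} (with
`around a` ≡ `0.9a < x < 1.1a`), verbalizes in interrogative,
imperative and keyword forms, and filters paraphrases through an
entity-preservation rule.  Evaluation reports exact-match accuracy, a
corpus-level BLEU score on a 0–100 scale and a four-way error taxonomy
(syntax, query structure, relation, function).

A deterministic synthetic fixture generator (`generate_kg()`) produces
an OntoSpecies-like ontology and KG, so everything is testable without
downloads or trained models.

## Worked example

```r
library(chemkgqa)

fx     <- generate_kg(fixture_config(seed = 11))   # ontology + instances
schema <- load_schema(fx$ontology)
kg     <- kg_store(instances = fx$instances)

gd <- make_gold_dataset(schema, kg, n = 50, seed = 11)
gd$dataset
#> <qa_dataset> 50 examples
#> relations: 1: 28.0%, 2: 36.0%, 3: 36.0%
#> functions: higher: 12.0%, lower: 10.0%, inside: 6.0%, outside: 12.0%, around: 10.0%

e <- Filter(function(e) e$metadata$intent == "species_search",
            gd$dataset$examples)[[1]]
e$question
#> "chemical species that have a molecular weight outside the range
#>  between 80 and 51.8 and have a optical rotation higher than 7.361"

pr <- run_pipeline(e$question, gold_backend(gd$gold_map), schema, kg)
pr
#> <pipeline_result>
#> result rows: 17; stages [ms]: preprocess=6.0 prompt=0.0 translate=0.0
#>   decode=0.0 copy_correct=4.0 relation_correct=6.0 expand=9.0 execute=36.0

head(pr$result_table[, c("IUPACNameValue", "UnitValue", "RefStateValue")], 3)
#>           IUPACNameValue UnitValue RefStateValue
#> 1          octan-1-thiol   g / mol          <NA>
#> 2   2-aminononenoic acid   g / mol          <NA>
#> 3 2-methylpenten-1-amine   g / mol          <NA>
```

The 17 rows are the species whose molecular weight lies outside
(51.8, 80) g/mol *and* whose optical rotation exceeds 7.361 deg; the
expansion pass added the IUPAC name and unit columns, and
`RefStateValue` is `NA` where no reference state is recorded (the
pattern is `OPTIONAL`).  Scoring the backend's predictions against the
gold queries:

```r
evaluate_translations(data.frame(gold = e$encoded_query,
                                 predicted = pr$predicted_encoded))
#> <eval_report> n=1  accuracy=100.00%  corpus BLEU=100.00
```

## Command-line use

Thin wrappers over the same functions live in `inst/cli/`:

```sh
Rscript inst/cli/make-fixtures.R    --n-species 30 --seed 1 --out fixtures
Rscript inst/cli/generate-dataset.R --ontology fixtures/ontology.ttl \
    --kg fixtures/instances.ttl --sizes 40,5,5 --seed 1 --out dataset
Rscript inst/cli/ask.R --question "what is the boiling point of octan-1-thiol?" \
    --ontology fixtures/ontology.ttl --kg fixtures/instances.ttl --backend rules
Rscript inst/cli/evaluate.R --pred pred.jsonl --gold dataset/dataset.jsonl \
    --ontology fixtures/ontology.ttl --report report.json
```

## Scope

The SPARQL executor covers the SELECT fragment the generator emits
(basic graph patterns with variables in any position, VALUES, numeric
FILTERs, OPTIONAL) over in-memory Turtle data or a SPARQL endpoint.
OWL reasoning, SPARQL UPDATE, aggregates and property paths are out of
scope, as are fine-tuning runs and quantization internals — see the
methods vignette (`vignettes/chemkgqa-methods.Rmd`) for the design
rationale and known limitations.
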