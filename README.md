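# nutriminer

Information extraction for the diet–microbiome literature, in R.

Papers on nutrition and the gut microbiome assert findings like
*"inulin increased fecal Bifidobacterium abundance in adults"*. Much of
this evidence stays buried in prose. `nutriminer` turns such statements
into structured records through a three-stage pipeline:

1. **Entity and trigger recognition** — span classification over all
   candidate token spans, encoded with *packed levitated markers*:
   marker pairs that share position indices with a span's boundary
   tokens and, under a directional visibility mask, interact only with
   their partner and the text, so many spans are encoded in one pass.
   One joint feedforward head covers 15 entity types (Food, Nutrient,
   DietPattern, Microorganism, …), 13 trigger types, and null; nested
   mentions are handled naturally.
2. **Relation extraction** — span-pair classification with
   subject-oriented packing (solid markers around the subject,
   levitated markers on candidate objects) into 13 relation types
   (`increases`, `decreases`, `affects`, `associated_with`, …) or
   null. A trigger-aware variant packs (subject, trigger, object)
   triples, using the trigger as a key for selecting objects.
3. **Factuality detection** — each extracted relation gets a coarse
   certainty in {Factual, Negated, Uncertain}, the three-way collapse
   of a six-level annotation scale.

Around the models, the package provides the full corpus toolchain:
brat-style standoff reading/writing (nested and discontinuous
mentions, event- and relation-style lines, certainty attributes),
schema validation, deterministic sentence segmentation and
sentence-bound filtering, corpus statistics, strict/relaxed evaluation
with bootstrap confidence intervals, inter-annotator agreement, a
deterministic synthetic corpus generator with an exact ground-truth
ledger, and an offline harness for zero-/one-shot relation extraction
with chat-completion models.

Scoring follows the field's conventions: a predicted mention is a
relaxed true positive when it overlaps a gold span of the same type,
and a strict one when the boundaries also match exactly; a relation
requires both arguments to match (direction respected for directional
types), and *end-to-end* scoring additionally requires the predicted
certainty, so for every run
F1(end-to-end) ≤ F1(relation) ≤ F1(relation, relaxed).

## A worked example

```r
library(nutriminer)

# generate a synthetic corpus (250 docs) and split it 200 train / 50 test
gen  <- generate_corpus(generator_config(seed = 101))
man  <- make_split(gen$manifest, c(0.8, 0, 0.2), seed = 101)
train <- gen$corpus[man$doc_id[man$split == "train"]]
test  <- gen$corpus[man$doc_id[man$split == "test"]]

# train the three stages against the frozen deterministic encoder
enc <- frozen_encoder(seed = 13)
cfg <- train_config(seed = 13)
models <- list(
  tagger          = train_span_tagger(train, enc, cfg),
  relation        = train_relation_classifier(train, enc, cfg),
  relation_triple = train_relation_classifier(train, enc, cfg, use_triggers = TRUE),
  factuality      = train_factuality_classifier(train, enc, cfg))

# run end-to-end on held-out documents and score
gold <- lapply(test, function(d)
  filter_sentence_bound(segment_sentences(d), drop = TRUE))
pred <- run_pipeline(test, models, use_triggers = TRUE)
glance(score_task(gold, pred, "ner", "strict"))
#> # A tibble: 1 x 9
#>   task  mode   require_certainty    tp    fp    fn precision recall    f1
#>   <chr> <chr>  <lgl>             <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 ner   strict FALSE               467    12     9     0.975  0.981 0.978
glance(score_task(gold, pred, "end2end", "strict"))$f1
#> [1] 0.8766234
```

The first call says that of the 476 gold entity mentions in the test
documents, 467 were recovered with exact boundaries and types (12 spurious,
9 missed). The second is the headline number: the fraction of gold
relations recovered end-to-end — correct arguments, relation type *and*
certainty — harmonically averaged with its precision. Ablations with
`gold_entities = TRUE` / `gold_triggers = TRUE` reproduce the usual
ladder (relation scores rise substantially when gold mentions, and then
gold triggers, are injected).

`corpus_statistics()` prints the descriptive table a corpus paper
reports — totals and medians by section, per-type distributions,
relation/trigger ratios, nesting/discontinuity/cross-sentence rates,
certainty distribution — and is checked to reproduce the generator's
ledger exactly. `compute_iaa()` scores one annotator against the other
(exact/partial, with and without trigger matching). `run_icl()` +
`evaluate_icl()` drive any `complete(prompt) -> text` model over
gold-entity pairs with filtered multiple-choice prompts and kNN-retrieved
demonstrations.

A thin command-line front end over these functions ships in
`inst/cli/nutriminer.R` (`generate`, `stats`, `validate`, `split`,
`evaluate`).

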