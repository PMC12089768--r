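---
title: "Extracting diet-microbiome associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting diet-microbiome associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriminer)
```

## The task

Scientific papers on nutrition and the gut microbiome assert relations
like *"inulin increased fecal Bifidobacterium abundance in adults"*.
Turning such statements into structured records requires four coupled
decisions: which text spans are entities (here: a Nutrient and a
Microorganism), which span signals the relation (the trigger
*increased*), which typed relation holds between which arguments
(`increases`, with an Agent and a Theme), and how certain the authors
are about it (factual, negated, or hedged).  `nutriminer` implements
this pipeline end to end, together with the corpus infrastructure
around it: brat-style standoff I/O, schema validation, strict/relaxed
evaluation, inter-annotator agreement, and a synthetic corpus generator
that makes every stage testable offline.

## The data model

The annotation schema fixes 15 entity types (Food, Nutrient,
DietPattern, Microorganism, DiversityMetric, Metabolite, Physiology,
Disease, Measurement, Enzyme, Gene, Chemical, Methodology, Population,
Biospecimen) and 13 relation types.  Most relation types are
directional with an explicit Agent and Theme; `associated_with` and
`interacts_with` are symmetric with two Themes and no direction.
Relations may be anchored on a trigger mention typed by the relation it
signals.  Certainty is annotated on a six-level ordinal scale (Factual,
Probable, Possible, Doubtful, Negated, Unknown) and coarsened to three
levels for classification: Factual, Negated, and Uncertain (the union
of Probable, Possible, Doubtful and Unknown).

Mentions may be nested (a Nutrient inside a longer Food phrase; depth
at most 2 in practice, which validation treats as a warning threshold,
not an error) and about 2% are discontinuous, stored as `;`-separated
fragment lists with 0-based half-open character offsets, the brat
convention.  Both relation dialects found in brat exports are read:
event-style lines anchored on a trigger and plain relation lines with
an optional trigger argument; the writer emits event-style whenever a
trigger exists, and factuality rides on attribute lines.

## Span recognition with packed levitated markers

Entity and trigger recognition is cast as span classification: every
token span up to a maximum width (default 8 word tokens; the published
figure of around 5 is treated as illustrative, and diet-pattern or food
phrases are frequently longer) is a candidate, classified into one of
15 entity types, 13 trigger types, or null by a single feedforward
layer — a 29-way joint head, so entities and triggers share the
candidate machinery.  Span prediction handles nested mentions
naturally: overlapping non-null decisions are all emitted, and ties
with the null label are resolved toward null, a precision-conservative
choice.

Rather than encoding each span separately, spans are packed as
*levitated marker* pairs: a start/end marker pair appended after the
token sequence that shares position indices with the span's boundary
tokens.  Directional attention lets each levitated marker see only its
partner and the text, while text tokens never see the markers, so many
spans are encoded in one pass without influencing each other — a
property the test suite checks numerically (representations are
invariant to unrelated pairs in the same pack, within 1e-5).
Candidates sharing a start token are packed together
(neighborhood-oriented packing, cap of 30 pairs per pack by default) so
the model can compare adjacent boundaries; a start group is split only
when it alone exceeds the cap.

For relation classification the subject span is wrapped in *solid*
markers physically inserted into the token order, and candidate
objects ride along as levitated pairs (subject-oriented packing).  The
trigger-aware variant solid-marks the (subject, trigger) pair as the
key for selecting objects (subject-trigger-oriented packing): with 3
entities and 1 trigger in a sentence, each entity serves as subject
with the other two as objects, yielding 6 triples.  A triple is a
positive training instance only when the gold relation between its
subject and object is anchored on that trigger.

Discontinuous gold mentions are collapsed to their minimal covering
contiguous span for candidate generation — a span enumerator cannot
emit gaps — while the exact fragment lists are kept in I/O and used by
the evaluator.  Under strict matching this places a small, known
ceiling on recall proportional to the discontinuity rate.

## The encoder

The package does not ship a pretrained transformer; the recognition
and classification stages are written against an encoder contract
(tokenization with character offsets, per-row contextual vectors,
shared position indices, a pairwise visibility mask).  The bundled
implementation is a compact deterministic encoder: token and position
embeddings are frozen pseudo-random vectors derived from a seed, and
two layers of visibility-masked attention use *disentangled* scores —
attention weights come from position embeddings (so a marker attends
sharply to the tokens whose positions it shares, controlled by a
`sharpness` temperature, default 3) while values come from a token
content stream (so no position noise leaks into span content).  The
output concatenates this attended representation with a sum-pooled
context channel over the visible text, which keeps cue words elsewhere
in the sentence (negation and hedging cues, trigger verbs) linearly
accessible from marker rows with a magnitude independent of sentence
length.

Only the heads on top of the encoder are trained: multinomial softmax
regression by full-batch gradient descent with momentum (default 250
epochs, learning rate 1, momentum 0.9, ridge penalty 1e-4), minimizing
cross-entropy, with the per-epoch loss kept on the fitted model
(`tidy()` on a fitted model returns the loss path).  The feature map
concatenates the start and end marker vectors and adds their
elementwise product, which lets the convex linear head express
start-AND-end conjunctions (e.g. a three-word Food phrase whose
boundary words individually also occur in null spans).  Class-balanced
sample weights with exponent 0.5 (`class_weight_alpha`) lift recall on
rare relation types, which occupy under 1% of the label mass, without
flooding frequent ones.  The factuality head uses a stronger ridge
penalty (1e-3): certainty hinges on a handful of cue-word directions
in the context channel, and heavier shrinkage steers the head toward
those shared directions instead of per-instance span idiosyncrasies.
Training is deterministic given data, encoder seed and head seed; the
default multi-run protocol averages over seeds.

## Pipeline and ablations

`run_pipeline()` chains the three stages on predicted upstream output:
mentions from the tagger, relations from the pair- or triple-mode
classifier, then a coarse certainty for every extracted relation (the
pipeline order means factuality is only ever predicted for extracted
relations).  Gold-entity and gold-trigger injection modes reproduce the
standard ablation ladder — end-to-end on predictions, relation
extraction on gold entities, and on gold entities plus triggers — whose
ordering is asserted as a test invariant.  In triple mode, sentences in
which no trigger was predicted fall back to the pair-mode classifier,
avoiding a silent recall loss; whether the original systems used such a
fallback is not documented, so the package makes it explicit and
optional (pass no `relation` model to disable it).  All non-gold
ordered pairs of a sentence are null training instances — no
subsampling by default, which matches the observation that around 90%
of candidate pairs in realistic data are null — and symmetric types are
trained in both orders and canonicalized (earlier span first) at
output, with duplicate predictions merged keeping the maximum score.

Experiments are restricted to sentence-bound relations: a relation
whose arguments and trigger do not all fall inside one sentence is
excluded by `filter_sentence_bound()` (cross-sentence relations are
roughly a tenth of the data and considerably harder; they are kept in
the corpus representation and the statistics, just not modelled).
Sentence segmentation is recomputed deterministically with a fixed
abbreviation list; a boundary that would split an annotated mention is
moved past that mention, and genus initials ("B. longum") do not end
sentences.

## Evaluation

`score_task()` reports micro-averaged precision, recall and F1 pooled
over documents, plus per-class counts.  Strict matching requires exact
fragment lists and the same type; relaxed matching requires character
overlap (computed on the envelope of discontinuous mentions) and the
same type.  Matching is one-to-one and greedy by maximal overlap with
deterministic tie-breaks, verified in the tests against an exhaustive
bipartite oracle on small instances.  Relation matching requires both
arguments to match per mode and the types to be equal, with direction
respected for directional types and order-free matching for symmetric
ones; trigger matching is never required for relation scoring.
End-to-end scoring additionally requires the coarse certainty to agree,
so end-to-end F1 can never exceed relation F1.

Factuality scoring ships two denominator conventions, because
"restricted to correctly identified relations" is ambiguous about
recall: the default scores precision over matched relations but keeps
all gold relations in the recall denominator (so missed relations
depress recall — the convention consistent with a published pattern of
near-perfect precision against recall only slightly above one half),
while the alternate mode restricts both to matched relations.  The
report records which mode produced it.

Bootstrap confidence intervals resample documents with replacement
(percentile method, 95%, B = 1000 by default, deterministic under a
seed); the document is the resampling unit because annotations within
a document are not independent.  Inter-annotator agreement is the F1
of one annotator's annotations scored against the other's — symmetric
by construction — reported as exact (strict boundaries) and partial
(overlap) for entities and for relations with and without a trigger
matching requirement; dropping the trigger requirement can only raise
relation agreement, which is asserted as an invariant.

## The synthetic corpus generator

`generate_corpus()` emits schema-conformant standoff corpora from
sentence templates of the form
`[Agent] [certainty-cue] [trigger] [Theme] in [Population].`, with
symmetric-relation sentences of the form
`[Theme] [trigger] with [Theme] in [Biospecimen] samples.`  Every
relation's trigger cue appears in-sentence, and certainty is realized
by deterministic cue words ("never" for Negated, "possibly" for
Possible, "likely" for Probable, "questionably" for Doubtful,
"reportedly" for Unknown; Factual carries no cue).  The defaults
encode the statistical structure the pipeline assumes in real corpora
of this kind: 5% nested mentions at depth 2 (built as an inner
Nutrient inside a three-word Food phrase), 2% discontinuous mentions
(two fragments separated by an interrupting modifier, mimicking the
coordination ellipsis that produces them in real text), 11%
cross-sentence relations (an `associated_with` link between entities
of adjacent sentences, certainty Unknown), a relation-type
distribution dominated by `increases`, `affects` and `decreases` with
five types below 1%, and a certainty distribution dominated by Factual
with Unknown carrying about three quarters of the uncertain mass.
Per-slot probabilities are derived from the configured global rates,
and the generator records an exact ground-truth ledger — counts per
type, nesting/discontinuity/cross-sentence tallies, certainty tallies
and sentence boundaries — that the statistics module must reproduce
exactly, which is the package's strongest end-to-end I/O check.

Two vocabulary regimes are provided.  In the default *type-revealing*
regime every surface form belongs to exactly one entity type, so span
labels are recoverable from the text and recognition failures indicate
machinery bugs rather than genuine ambiguity; the *ambiguous* regime
shares some surfaces across types for robustness checks.  This is the
deliberate limit of what passing tests show about real data: the
generator emulates the *structural* properties of diet-microbiome
annotation (nesting, discontinuity, triggers, cues, skew) but not
lexical ambiguity, paraphrase, long-range syntax or annotation noise,
so recovery scores on it are an upper bound sanity check of the
machinery, not a performance claim about the published benchmark.

The default study conditions train on 200 documents and test on 50
(three sentences per document), with three run seeds; at that size the
full three-seed recovery experiment runs in a few minutes on one CPU.

## Zero- and one-shot extraction

The in-context-learning harness performs relation + certainty
extraction over gold entities through a provider-agnostic
`complete(prompt) -> text` contract, so any chat-completion backend —
or a mock — plugs in.  Prompts contain a task description, a guideline
listing only the relation types observed at least 3 times between the
two entity types in the training corpus (pairs with an empty choice
set are skipped and logged), an optional demonstration retrieved by
cosine similarity between sentence embeddings (deterministic ties by
pool index), and the test sentence with the two gold mentions wrapped
in offset-based markers, followed by three multiple-choice questions:
relation or not, which type, and which certainty.  Answer parsing is
total: unparseable completions and answers outside the offered choice
set yield "no relation" with a logged parse failure.  An oracle mock
that answers from gold must drive the harness to F1 = 1, which is the
plumbing-correctness test.  Evaluation optionally restricts prompting
to pairs known to hold a relation, the variant that isolates type
classification from null detection.

## Numerical and design notes

* All offsets are 0-based half-open; token spans are 0-based inclusive
  at the word level, mapped to characters through the tokenizer's
  offset table.
* Encoding saves and restores the global RNG state, so inference never
  perturbs user-level reproducibility; the generator and all training
  entry points take explicit seeds, and the same seed yields
  byte-identical corpora and identical fitted weights.
* Zero-denominator precision/recall cases are reported as 0; F1 of an
  empty prediction set against an empty gold set is 0 by this
  convention, which only arises in degenerate fixtures.
* The bootstrap gives bootstrap replicates fresh document ids so that
  repeated documents in a resample stay paired by position.
* Known limitations: discontinuous mentions cannot be emitted by the
  span enumerator (strict-recall ceiling equal to the discontinuity
  rate); cross-sentence relations are represented but not modelled;
  the bundled encoder is a deterministic stand-alone component, not a
  pretrained language model, so absolute scores on real corpora will
  differ; and the trigger-aware relation model requires trigger
  predictions of reasonable quality before it pays off, which is why
  both the pair-mode and triple-mode classifiers are kept.
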