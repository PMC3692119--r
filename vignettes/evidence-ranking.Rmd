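---
title: "Ranking evidence sentences: model, features and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking evidence sentences: model, features and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evisent)
```

`evisent` ranks sentences from annotated biomedical abstracts by how
strongly they assert that a gene is involved in the development of a
cancer through a biological event. This vignette explains the model and
its assumptions, the tunable parameters, the synthetic-data generator
that the tests rely on, and the design decisions taken where the problem
left genuine choices open.

## The ranking model

### Candidates

The unit being scored is a (gene mention, event trigger) pair inside one
sentence. A sentence is eligible when it carries at least one gene and at
least one event trigger that survives pre-screening, and a cancer term
occurs in the sentence or anywhere else in its abstract. Pre-screening
removes trigger words that are blacklisted for their event type (for
transcription: "described", "derived", "prescribed", "transition") and
localization triggers that are cytogenetic band names (`17q21`, `8p11.2`,
`Xq28`), which denote chromosomal, not sub-cellular, locations.

Scoring pairs rather than whole sentences keeps the features
well-defined — a sentence can mention several genes and events whose
evidential quality differs. The sentence (and, at display time, the
abstract) inherits the maximum over its pairs, matching a service that
shows one best sentence per abstract.

### Features

Ten features describe each candidate:

| feature | type | source |
|---|---|---|
| `norm_event_score` | [0, 1] | trigger classifier score, min–max normalized in the batch |
| `norm_edge_score` | [0, 1] | trigger–gene edge score, likewise |
| `gene_event_dist` | edges or penalty | dependency path, gene anchor to trigger anchor |
| `event_regulation_dist` | edges or penalty | trigger to nearest regulation connective |
| `event_cancer_dist` | edges or penalty | trigger to nearest cancer term |
| `cancer_count` | count | cancer-lexicon occurrences in the sentence |
| `hallmark_count` | count | the six hallmark keywords |
| `event_depth` | count | edges from the tree root to the trigger |
| `negative_score` | count | purpose/negation cue occurrences |
| `agent_present` | boolean | another gene in a different branch of the event |

Multi-token mentions are represented by their **anchor**: the rightmost
token of the span whose head lies outside the span (the syntactic head;
English noun compounds are head-final). Distances are edge counts on the
undirected dependency tree; when a regulation or cancer term is missing
from the sentence the configured penalty constant (default 10) stands in.
The penalty is deliberately binned as its own category, so its magnitude
never matters beyond marking absence; a genuine path of exactly 10 edges
would fall into the same bin, which we accept as a rare and semantically
harmless collision.

Raw classifier scores are comparable only within one result set, so they
are min–max normalized within the batch being scored. Normalizing by the
batch maximum alone is not well-defined when raw SVM scores are negative,
which is why the package uses min–max instead; a constant batch maps to
0.5 and a missing score to 0. Keyword features count *occurrences*, not
distinct terms; on the bundled positive example the two readings agree,
and occurrence counting keeps the feature monotone in repetition.

The **agent** rule deserves a note. The intent is to spot sentences whose
event links two genes rather than a gene and the disease. We require the
trigger's anchor to be a proper ancestor of the query gene's anchor, and
call any other gene an agent when it lies in the trigger's subtree but is
reached through a *different child* of the trigger. A stricter
direct-child-only reading fails on the bundled worked example, where the
agent hangs one level below the event's subject branch; "other branch of
the event" is the generalization that covers it.

### The likelihood ratio

With equal class priors, the ranking statistic is the log likelihood
ratio of the binned features. Eight features enter independently
(naive-Bayes style); two enter through explicit dependencies:

* `cancer_count` is conditioned on a coarse zone of
  `event_cancer_dist` — *near* (< 4 edges), *far* (≥ 4) or *absent*
  (penalty). The presence of a cancer keyword matters most when the
  cancer name does not co-occur near the event keyword.
* `agent_present` is conditioned on hallmark presence
  (`hallmark_count > 0`). An agent normally signals a negative sentence,
  but not when a hallmark keyword appears alongside it.

Continuous features are discretized by equal-frequency quartiles fitted
on the pooled training data, with dedicated bins for zero and for the
penalty. Equal-frequency binning is robust to the heavy-tailed count
distributions involved and never produces empty training bins by
construction; the quartile granularity keeps every conditional table
estimable from a few hundred labeled sentences. All tables are add-alpha
smoothed (`alpha = 1`), so probabilities are strictly positive, and a bin
never seen at fit time scores at the smoothed floor.

The log ratio is converted to a display score in (0, 1) by a sigmoid
(`slope = 1` by default; any positive slope gives the same ranking).
Localization candidates whose sentence names no sub-cellular compartment
are demoted by multiplying the score by `localization_factor` (default
0.5). The demotion is applied after the sigmoid, in score space: it is a
presentation-layer re-ordering between two well-defined groups, and
score-space multiplication keeps it bounded and order-preserving within
each group. Ranking ties are broken deterministically by
(abstract id, sentence id, gene id).

Defaults in one place: penalty 10, `alpha` 1, sigmoid slope 1,
localization factor 0.5, binning by quartiles — all overridable through
`fit_evidence_model()` arguments.

## Evaluation protocol

Performance is measured by stratified 5-fold cross-validation (fold
assignment is label-stratified and seeded; the default seed is 42).
For the headline figure, every attained cutoff *fraction* is swept:
in each fold the top `round(fraction * fold size)` candidates are called
positive, F-measures are averaged across folds, and the fraction with
the highest average F is reported (ties to the smallest fraction).
Aligning folds by fraction rather than absolute k makes the average
well-defined when folds differ in size by one. AUC is the Mann–Whitney
rank statistic (ties count one half), averaged over folds.

The random-order baseline assigns i.i.d. uniform scores, applies the same
best-cutoff machinery to each ordering, and averages 100 repetitions.
Because a random ranking's F-measure is maximized near the bottom of the
list, its recall approaches 100% and its precision the positive-class
rate — a useful sanity floor for any ranker. Single-feature ablation
refits the model restricted to one feature at a time, with the two
dependent features keeping their conditioning variable.

## The synthetic-data generator

No labeled gold corpus of evidence sentences is redistributable, so the
package ships a generator that emulates one. `synth_params()` controls,
per class, the probability that a cancer term appears in the sentence
(and its distance to the trigger), the hallmark, negative-cue,
regulation-term and agent rates, the gene–event distance and trigger
depth distributions, the classifier-score ranges, and the event-type
mixture. Sentences are built from parse-tree templates: a root verb,
chains of filler tokens realizing the sampled path lengths exactly, and
slot-filled lexicon tokens; every output is a valid single-rooted tree
with consistent mentions, and the whole corpus is a deterministic
function of the seed.

The `"paper-like"` preset represents a 563-sentence gold corpus
(207 positive / 356 negative, the event mixture weighted toward gene
expression). Its per-class parameters were chosen once so that the
realized single-feature informativeness profile matches what is reported
for this family of features on real data — event–cancer distance and
cancer count clearly strongest, classifier scores, event depth,
gene–event distance and agent presence close to chance, cue counts in
between — and so that the classes are well separated (the full model
reaches cross-validated AUC above 0.90 on this preset, and beats every
single feature). The `"uninformative"` preset equalizes both classes and
serves as the null corpus.

What the generator does *not* emulate: natural word order and fluency
(sentences are feature-faithful, not prose-faithful), correlated noise
between features beyond the modeled dependencies, annotation errors from
upstream NER/event extraction, and the long-tail vocabulary of real
abstracts. Tests passing on synthetic corpora therefore validate the
machinery — feature extraction, fitting, the protocol — not real-world
accuracy figures, which depend on the (unavailable) manually labeled
corpus.

Problem sizes used by the test suite were chosen to keep every law-of-
large-numbers check stable: rate-recovery tests use 2000 sentences,
cross-validation properties the 563-sentence preset, and oracle
equivalences run on instances of up to 30 items against exhaustive
brute-force references.

## Degenerate inputs and numerical corners

* Empty candidate sets produce empty (typed) feature frames; an empty
  annotation block yields a sentence with no mentions.
* A constant score batch normalizes to 0.5 everywhere; missing scores
  to 0.
* Quartile edges collapse when a feature takes few distinct values; the
  bin label set shrinks accordingly and smoothing covers the rest.
* Fitting requires both classes; AUC requires both classes; stratified
  folds require at least k examples per class. Each raises an error
  rather than returning a misleading number.
* Dependency trees are validated on construction (single root, heads in
  range, acyclic); CoNLL input with two roots or a cycle is rejected.

## Known limitations

* Upstream annotations are trusted as given: no NER, normalization,
  parsing or event extraction is performed or corrected.
* The regulation-term and negative-cue lexicons are compact curated
  lists; domain-specific vocabularies may need the override files.
* Only 3 of the 12 default cancer-lexicon entries are documented by the
  method's source material; the remaining entries are a reconstruction
  from standard oncology vocabulary and should be overridden when a
  better list is available.
* The inverted index is an in-memory structure intended for corpora of
  thousands of sentences, not a production search engine.
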