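---
title: "Typed inconsistency synthesis and consistency classification for GO annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed inconsistency synthesis and consistency classification for GO annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goac)
```

## The problem

A literature-based Gene Ontology annotation (GOA) pairs *evidence
information* — a sentence (or concatenated sentences) from a full-text
article, its location in the article, and a GO evidence code — with *GO
information*: a term accession, the term string, and its definition.
Curators must keep these two halves consistent as the literature and the GO
vocabulary evolve, and manual re-review does not scale. `goac` implements a
complete desk-scale framework for studying automatic consistency assurance:
it synthesises labelled inconsistencies from consistent, evidence-grounded
annotations, trains and scores consistency classifiers, and analyses where
and why predictions are uncertain.

Writing an instance as the triple $(\epsilon, \theta, \gamma)$ — evidence
information, GO information, evidence code — each instance carries exactly
one consistency label $y$:

* **consistent** — the evidence supports the term and code as annotated;
* **A (contradictory)** — the regulation polarity of the term contradicts
  the evidence ("positive regulation of …" vs an inhibiting finding);
* **B (over-specific)** — the term is a descendant more specific than the
  evidence supports;
* **C (unsupportive)** — the evidence text mentions the GO concept but does
  not express gene-function information;
* **D (erroneous code)** — an experimental evidence code that does not match
  the kind of experiment described.

The single-label assumption (one inconsistency at a time, independent types)
is a modelling simplification: a Type C instance can often also be read as
Type B, and the discussion of that overlap is exactly why per-type error
analysis matters. Types A–C concern $P(y \mid \epsilon, \theta)$ and are
handled by the four-class **term task**; Type D concerns
$P(y \mid \epsilon, \gamma)$ and is the binary **code task**. The class
orders are fixed — `consistent, A, B, C` and `consistent, D` — so the index
$i$ in a probability vector $P_i$ is unambiguous.

## Inconsistency synthesis

`make_consistent()` turns a raw annotation into a consistent instance:
multi-sentence evidence is concatenated in document order with single
spaces, the definition and synonyms are filled from the ontology graph, the
raw section title is normalised, and annotations on obsolete terms are
skipped. Each injector then applies one *minimal* edit, and the package
enforces that minimality as an invariant (a Type A/B instance differs from
its source only in GO fields, C only in evidence text/spans/section, D only
in the code):

* **Type A** swaps "positive regulation" ↔ "negative regulation" in the
  term string and re-resolves the swapped name in the graph; if the sibling
  term does not exist the instance is skipped — no accession is ever
  fabricated. The swap is an involution on term strings.
* **Type B** replaces the term with a direct is_a/part_of descendant.
  Strategy `random` draws uniformly (seeded) over the accession-sorted
  candidates; strategy `overlap` takes the descendant with the greatest
  word overlap with the parent name ("feeding behavior" overlaps "suckling
  behavior" once and "regulation of feeding behavior" twice, so the latter
  is chosen). Leaf terms are skipped. In a full dataset build the overlap
  strategy is applied to a seeded 20% of training articles and the random
  strategy everywhere else, so a model cannot simply learn that large term
  overlap means over-specific.
* **Type C** replaces the evidence sentence with the most similar
  *unsupportive* sentence of the same article: every passage is segmented,
  sentences overlapping any evidence span of any instance in the article
  are excluded (the strict reading of "not annotated means unsupportive"),
  the remainder is filtered to sentences in which dictionary-based concept
  recognition finds the instance's GO concept, and the candidate with the
  highest cosine similarity to the original evidence wins. The source's
  evidence type and code are kept; the section fields are updated to the
  replacement's passage.
* **Type D** applies only to experiment-type instances with a code in
  {IDA, IMP, IPI, IGI, IEP}; summary sentences (code "NONE") do not support
  code selection and are skipped. The replacement is a seeded uniform draw
  from the remaining experimental codes, never the original.

Every injected instance records provenance (source instance, strategy,
seed), and an identical configuration reproduces a byte-identical dataset.

### Concept recognition

The recogniser is a transparent longest-match dictionary lookup over term
names and synonyms, normalised by lowercasing and whitespace collapse, with
light suffix stripping (`-s`, `-es`, `-ic`, `-al`) at query time so
adjectival mentions such as "cytosolic" map to "cytosol". Matches respect
token boundaries, are non-overlapping, and prefer the longest entry. This
is deliberately simpler than pipeline recognisers built on permutation-
tolerant dictionaries: it is deterministic, dependency-free, and its
failure modes are inspectable. It will not find concepts that appear only
implicitly ("Ca2+-promoted fusion activity" is not a mention of "positive
regulation of vesicle fusion"); that limitation is inherited by Type C
candidate selection.

### Sentence similarity

The default similarity backend is TF-IDF over the supplied sentence set
with cosine similarity; zero vectors compare as 0 and ties go to the
earliest candidate sentence. Pretrained sentence embeddings can be swapped
in behind the same `embedding_backend` interface; TF-IDF is the default
because it is deterministic and adequate for ranking candidates that
already share a recognised concept with the evidence.

## Classifiers

Two baselines and one learned model are provided, all emitting probability
vectors on the task simplex with Shannon entropy attached.

The **prior-biased classifier** predicts by a seeded categorical draw from
the training label distribution (an argmax variant is available). Its
expected per-class precision equals the class's test-set prevalence, which
the test suite checks analytically. The **section rule** predicts
unsupportive (C) whenever the evidence section is Background, Supporting
information, Supplementary or Other, and otherwise draws from a fallback
prior over the non-C classes. Conclusion-section instances are treated as
consistent-side for determinism; they are rare enough not to matter
statistically. The published redistribution probability for the
over-specific class is not derivable from the published count table under
any single prior, so the fallback prior is a caller-supplied argument
rather than a hard-coded constant.

The **lexical classifier** is the in-core learned model: multinomial
logistic regression (`nnet::multinom`) over transparent features — the
term/evidence and definition/evidence token-overlap ratios, the
evidence-to-definition length ratio, the term token count, a
regulation-polarity mismatch indicator between term and evidence lexicon, a
result-framing indicator, section one-hots, and for the code task the code
one-hot plus overlap with a small evidence-code keyword vocabulary.
Training rows are canonically ordered by instance id before fitting, so the
fit is invariant to input permutation, and the optimiser is seeded. The
features are intentionally the same quantities the linguistic test suite
measures, so the model's error modes are inspectable in the same vocabulary
as the error analysis.

Fine-tuning a biomedical BERT on the rendered sequence pairs
(`"[CLS] evidence [SEP] term: definition [SEP]"`, with a section encoding
concatenated to the 768-dimensional [CLS] state) is out of scope for an
offline package; `transformer_backend_contract()` instead emits the exact
input files and the hyperparameter manifest (AdamW, weight decay 0.01, 300
warmup steps, 3 epochs, batch sizes 16/64, hidden 768, concatenated
dimension 769) for an external run.

## Evaluation

Metrics are grounded at the **evidence level**: if one of two evidence
sentences for the same term is misclassified, precision for that class is
0.5 even though the article-level call might look perfect. Precision is the
headline metric because a single detected inconsistency flags the whole
article for review — `article_flag()` computes exactly that, and recall at
article level is achieved by any one detection. For single-label
multi-class prediction, micro-precision and micro-recall coincide, and the
package verifies this identity on every evaluation. 0/0 precision or recall
is defined as 0 with the support recorded, so consumers can mask empty
classes.

Prediction uncertainty is Shannon entropy in bits,
$H = -\sum_i P_i \log_2 P_i$, bounded by 2 for the term task and 1 for the
code task. `uncertainty_collections()` clusters predictions into windows
$[\tau - \alpha, \tau]$ over an arithmetic grid of $\tau$; intervals are
closed on both ends because an instance whose entropy falls exactly on a
boundary is meant to be shared by two consecutive collections when
$\alpha$ equals the step. The default grid is $\tau \in [0.2, 1.7]$, step
0.1, $\alpha = 0.1$ — note this yields 16 collections while the companion
table layout of the original study lists 15 rows ($\tau \le 1.6$); the
bounds are arguments, and the default follows the stated range.
Floating-point grid values are compared with a $10^{-9}$ tolerance so that
entropies like exactly 1 bit land in both neighbouring windows regardless
of representation error.

The linguistic test suite scores each instance with **GOLen** (whitespace
token count of the term), **AlignRatio** (evidence tokens / definition
tokens) and **GEORatio** (distinct term∩evidence tokens / GOLen), and each
collection with **%ContainRoman**, **%ContainDigit** and **%ContainStop-OF**
— the fraction of members whose term contains an uppercase Roman-numeral
token (so "photosystem II" counts and a lone lowercase "i" does not), any
digit character, or the whole token "of". One tokenisation convention —
lowercase, whitespace split, punctuation retained — is shared by word
overlap, the test suite and the classifier features; it reproduces the
worked values 0.32 and 0.25 on the published example strings.
`pearson_analysis()` relates these scores to uncertainty in the two modes
used in practice: per-instance metric against per-instance entropy, and
per-collection aggregated metric against $\tau$.

## The synthetic data generator

`generate_ontology()` and `generate_corpus()` produce the study conditions
offline. The mini ontology is a DAG of term families under one root: base
process terms, "regulation of" children, positive/negative regulation
sibling pairs, and a specific is_a/part_of descendant per family, with a
configurable fraction of leaves, digit/Roman decorations, synonyms, and one
obsolete term. Accessions use the reserved range `GO:9xxxxxx` to avoid
collision with real GO ids.

The corpus emulates the structure of an evidence-grounded curation corpus:
sectioned articles; evidence sentences that embed the term name verbatim
together with a result-framing verb, a polarity verb agreeing with the
term's regulation direction, and (for experiment-type evidence) a keyword
phrase for the evidence code; and distractor sentences that mention
annotated concepts without gene-function framing. Evidence sections follow
the results-dominated distribution observed for consistent annotations
(80.6% results-and-discussion), distractors a flatter distribution — both
are config arguments. Articles draw annotated terms at term-family
granularity from a shared pool without replacement, so the siblings and
descendants that injection substitutes stay within one article; this is
what makes the great majority of test-set GO ids unseen during training,
the open-world condition the framework is meant to satisfy.

Because the lexical cues are planted by construction, desk-scale
learnability is a property of the generator, not of pretrained semantics:
passing tests demonstrate that the pipeline — generation, injection,
splitting, training, prediction, scoring — is correct end to end, not that
any classifier would reach these scores on real curation data, where class
signals are far noisier and partially absent.

## Numerical choices and defaults

* Coordinates are 0-based half-open character offsets throughout.
* Section normalisation is a case-insensitive keyword table onto the fixed
  10-category scheme with `Other` as the total fallback.
* The sentence segmenter is rule-based with an abbreviation list; it is
  pluggable, and its outputs on awkward inputs are frozen as regression
  expectations rather than asserted linguistically.
* Tie-breaks are all deterministic: overlap-strategy ties take the smallest
  accession, cosine ties the earliest sentence, argmax ties the lower class
  index.
* The development split is a seeded simple random sample (20% by default)
  of training-article instances; the test set comes only from test
  articles.
* Default problem sizes: the bundled test suite and the acceptance script
  run the pipeline at roughly 500 generated instances (25 articles, ~500
  ontology terms), which keeps a full generate→inject→train→evaluate cycle
  under a minute on one CPU while leaving every class populated.

## Limitations

The generator's sentences are structural stand-ins with no biological
semantics; gene/organism mismatches are assumed away; multi-label
inconsistencies are not generated; recognition is exact-surface only; and
the learned model is a feature-transparent stand-in whose scores on
synthetic data say nothing quantitative about transformer performance on
real corpora. The manual-confirmation step of a real curation study is
represented only as a review export (`review_export()`), a TSV for human
inspection.
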