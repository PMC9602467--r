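---
title: "Balancing imbalanced speech-transcript corpora by stopword-aware augmentation"
author: "speechaug authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing imbalanced speech-transcript corpora by stopword-aware augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechaug)
```

## The screening problem and the data model

Spontaneous speech carries early signals of cognitive decline: people with
dementia or mild cognitive impairment (MCI) use pronouns more often in
place of content words, show reduced lexical diversity (a lower type–token
ratio, TTR), and cover fewer of the salient events when describing a
stimulus. A practical screening protocol therefore elicits twelve short
monologues per subject — ten episodic-recall prompts (`EP1a` … `EP8a`),
one picture description and one animation description whose stimulus has
four story events — transcribes them, and asks a text classifier to
separate healthy controls (HC) from MCI.

Ground truth comes from the Mini-Mental State Examination, a 30-point
screening instrument. `assign_label()` implements the banding used
throughout the package: scores of 28–30 are `HEALTHY`, 23–27 are `MCI`,
and anything below 23 falls into the possible-dementia range and is
excluded from binary classification (`EXCLUDED_DEMENTIA_RANGE`). The bands
are contiguous and exhaustive over 0–30, which the test suite asserts by
enumeration.

A corpus is a tibble with one row per (subject, task) transcript. Two
provenance columns — `origin_id` and `augmentation_tag` — record, for
every row, which un-augmented sample it descends from and which operator
produced it. These columns are what make an honest evaluation possible
later: without them, augmentation leakage cannot even be measured.

## Cleansing

`clean_transcript()` removes corpus-specific recording markers (the
strings are configuration, not constants — transcription conventions
differ per corpus and the default marker set is empty), collapses line
breaks, and truncates to at most 512 tokenizer units, keeping the prefix.
The 512 limit matches the input window of the sentence encoders this
pipeline feeds; truncation operates on tokenizer units rather than raw
characters because the downstream limit is token-based, and the prefix is
kept because it is the only deterministic, order-preserving choice.
Cleaning is idempotent, and cleaned text never exceeds the limit —
both are property-tested.

The tokenizer is a pluggable contract (string → tokens, tokens → string,
with tokenize∘join idempotent on its own output). The default is
whitespace splitting; corpora of unsegmented text such as Japanese should
be pre-segmented by a morphological analyzer upstream, or inject their own
tokenizer.

## Stopwords and the synonym lexicon

Augmentation needs two lexical resources. A *stopword list* marks tokens
that must not be touched: replacing or inserting function words produces
degenerate augmented text. `load_stopwords()` reads a one-word-per-line
file and subtracts an exclusion set. The exclusion set matters
clinically: general-purpose stopword lists contain demonstratives and
pronouns, but pronoun frequency is exactly the kind of signal an MCI
classifier needs, so those entries are handed to `exclusions` and stay
visible to augmentation. Which entries of a published list count as
"directive-equivalent" is a judgment call the package deliberately leaves
to configuration; the shipped fixtures construct lists of the right shape
(the reference workflow arrives at 288 protected words from a ~310-word
general list minus ~22 such exclusions) without claiming to reproduce any
curated resource.

A *synonym lexicon* maps words to synonym sets (`word<TAB>syn1,syn2,…`);
self-maps are dropped, duplicate headword lines merge by union, and absent
words return the empty set, so synonym replacement degrades gracefully to
the identity where the lexicon has no coverage. A WordNet-derived table
can be dropped in; the test fixtures use `generate_fixture_lexicon()`.

## The four EDA operators

For a sentence of $l$ tokens, one operator application perturbs
$n = \max(1, \mathrm{round}(\alpha l))$ tokens. The default
$\alpha = 0.05$ follows the established recommendation for this family of
methods — larger $\alpha$ degrades label fidelity faster than it adds
diversity. The operators, each with its invariants:

* **Synonym replacement (SR)** replaces up to $n$ eligible tokens
  (non-stopword, nonempty synonym set) with uniform synonyms. At most $n$
  positions change; length is preserved; stopwords are never touched.
* **Random insertion (RI)** inserts $n$ tokens at uniform gaps. The
  default `DUPLICATE` mode copies a uniformly chosen non-stopword token of
  the sentence; `SYNONYM` mode (the classic formulation) inserts a synonym
  of such a token instead. Output length is exactly $l + n$, and the
  output multiset contains the input multiset.
* **Random swap (RS)** applies $n$ sequential transpositions of uniform
  position pairs; the output is a permutation of the input.
* **Random deletion (RD)** keeps each token independently with probability
  $1 - p$ (default $p = \alpha$); if everything is deleted, one uniform
  token survives, so nonempty input never yields empty output. The mean
  output length is $l(1-p) + p^l$, which the suite checks against 10,000
  simulated draws.

`augment_sentence()` turns one original into `n_out` samples: the
original first, then `n_out − 1` copies, each from exactly one operator.
Operator assignment follows a policy; the default `CYCLE` rotates
SR, RI, RS, RD deterministically, giving balanced operator coverage (a
uniform-random and a fixed-operator policy exist). Every copy inherits
the original's label, task, subject and `origin_id` — augmentation can
never relabel — and carries its operator's tag.

## Class balancing

`balance_augment()` applies a per-class multiplier: every MCI original
expands to 30 samples and every healthy original to 10 (defaults). The
multiplier counts total copies *including* the original — with 180 MCI
and 540 HC originals both readings of "augmented 30×/10×" land on
5,400 + 5,400 = 10,800, and including the original keeps the strongest
copy of the signal in the training set; `include_original = FALSE`
switches to the additive reading. Each original's augmentation stream is
seeded independently (derived from the plan seed and the row index), so
results are reproducible and insensitive to corpus ordering.

## Splitting and the leakage audit

The evaluation protocol this package replicates describes ten-part
cross-validation with 20% test and 10% validation. Those numbers are
internally inconsistent with classic 10-fold CV (whose folds would be
10%), so `make_splits()` implements what reproduces *all* stated numbers:
10 repeated stratified random splits at 70/10/20, stratification by label
with largest-remainder allocation (per-part class proportions within one
sample of the global ones, asserted in tests). Stratification by label
rather than task is the default because the label is the quantity whose
balance the whole pipeline exists to protect.

The critical design axis is *what* gets assigned to a side:

* `SAMPLE_LEVEL` — augmented samples independently (the replicated
  protocol);
* `ORIGIN_LEVEL` — all copies of one original together;
* `SUBJECT_LEVEL` — all samples of one subject together.

Sample-level splitting lets near-duplicates of a training sentence appear
in the test set. With ≥ 10 copies per origin and a 20% test fraction, the
probability that a test sample's origin is absent from training is
hypergeometrically small — the audit of the default augmented dataset
shows an origin-overlap fraction of essentially 1.0, and the test suite
verifies the audit against direct enumeration on a 12-origin toy dataset.
`leakage_audit()` reports these fractions for any split; the pipeline
prints them prominently. Origin- or subject-level splitting is the
recommended scientific mode; sample-level exists for protocol fidelity.
Grouped stratification fails loudly when a single group exceeds its class
quota rather than silently degrading.

## The classifier harness

Backends satisfy a four-function contract (`init`, `fit_epoch`,
`objective`, `predict`); `train_eval()` owns the loop: it evaluates the
validation objective once before training and after every epoch, keeps
the best-validation state, stops after `patience` consecutive
non-improvements (default 1, objective = validation log-loss), and caps
at 4 epochs. The harness hands the backend only training and validation
rows — a scripted mock backend in the test suite records every sample id
it is shown and proves the test set never reaches `fit`.

The hyperparameter grid crosses batch sizes 1–32 with learning rates
5e-5, 3e-5, 2e-5 (18 settings); `run_grid()` scores each by mean weighted
F1 over the split repeats and reports the argmax (ties to the first in
grid order: batch ascending, rate descending).

The shipped backend is a deterministic logistic classifier on
length-normalized term-frequency features (training vocabulary, most
frequent 512 tokens), trained by mini-batch SGD with L2 shrinkage. Batch
size maps directly onto the SGD mini-batch; the grid's learning rates are
quoted on the fine-tuning scale of encoder models, so the backend
multiplies them by a fixed `lr_scale = 1e4` to reach this optimizer's
working regime — the knob stays meaningful, and grid bookkeeping is
identical across backends. A fine-tuned transformer encoder is the
intended production backend behind the same contract; it is deliberately
not bundled, because the pipeline's subject of study is the augmentation
arithmetic, not the encoder.

## Evaluation

`weighted_f1()` is the support-weighted mean of per-class F1 (F1 defined
as 0 when precision + recall is 0), cross-checked in the suite against a
brute-force confusion-matrix scorer on a thousand random vectors, and
against the closed form for the all-majority predictor on a 45/15 cohort:
$0.75 \times \frac{2 \cdot 0.75}{1.75} = 0.643$.

`per_task_report()` breaks the test set down by task. Reference reports
of this protocol label the per-task column "rate of correct predictions"
while the surrounding text calls it F1; rather than guess, the report
carries *both* — within-task correct rate and within-task weighted F1 —
side by side. The average row is the unweighted mean over populated tasks
(so a 2,160-sample test set over 12 tasks averages 180.0 test samples per
task); tasks with no test samples are reported with `n_test = 0` and `NA`
rates rather than dropped.

## The synthetic corpus generator

Because clinical corpora of this kind are private, the generator is a
first-class module, not a test shim. `generate_cohort()` draws the
default study conditions: 45 HC / 15 MCI, group-conditional MMSE normals
(29.3 ± 0.7 and 25.9 ± 1.0), age 73.7 ± 4.1, sex alternating within
group. Sampled MMSE scores are rounded and clamped into the group's label
band, because the published summaries are conditional on group
membership; `assign_label()` then reproduces the intended cohort exactly.

`generate_sample()` emits token sequences, not grammatical prose — the
pipeline operates on token sequences, so statistical structure is the
goal and linguistic realism is a non-goal. Three group-dependent effects
carry the class signal, each a tunable knob with defaults chosen as
plausible mid-range values (the literature reports the direction of these
effects, not portable effect sizes):

* pronoun rate 0.08 (HC) vs 0.22 (MCI): each content slot independently
  becomes a pronoun; pronouns are a fixed inventory disjoint from topic
  vocabulary, so the realized rate is exactly measurable (the suite
  checks it within three standard errors over 220 samples per group);
* type–token ratio 0.7 vs 0.5: the content pool size is
  `round(ttr × length)` and every pool word appears at least once, so the
  realized TTR tracks the target;
* key-event coverage 0.9 vs 0.6 (picture/animation only):
  `round(coverage × 4)` event phrases inserted as contiguous runs in
  template order. Episodic templates have no key events — their content
  varies by subject — and rely on topic vocabulary alone.

Sample length is normal (mean 80, sd 15 tokens — a one-to-two-minute
monologue after tokenization) truncated at 1; fillers are sprinkled at
rate 0.05. Setting both groups' parameters equal produces a null corpus:
the suite confirms a classifier then scores indistinguishably from the
majority rate over five seeds, while maximally separated parameters
(pronoun rates 0 vs 1) yield near-perfect held-out accuracy. Passing
tests on this corpus therefore demonstrates that the pipeline's
*mechanics* — counting, balancing, protection, leakage, scoring — are
correct, and that augmentation recovers a plantable minority signal; it
does not certify performance on real clinical speech, whose signal
structure (syntax, disfluency, topic drift) the generator does not model.

## Numerical choices and determinism

* `n_changes` uses `max(1, round(α·l))` so every operator application
  does something; R's round-half-to-even is irrelevant here because the
  max(1, ·) floor absorbs the half-point cases at default α.
* Random deletion's never-empty rule adds $p^l$ to the expected output
  length; tests account for it.
* Grouped splits use first-fit assignment of shuffled groups against the
  class quota; with equal group sizes (the balanced default) quotas are
  met exactly.
* All drivers derive per-unit seeds from one user seed via a fixed linear
  congruential step (kept below $2^{31}$), so every stage is
  independently reproducible: same config + seed ⇒ byte-identical
  JSON-lines artifacts, which the pipeline test asserts literally.
* Pipeline artifacts embed an MD5 hash of the serialized configuration
  (in `manifest.json` and the JSON artifacts), and the run log records
  per-stage sample counts as an auditable conservation chain.

Problem sizes used by the shipped checks: the full default corpus (720 →
10,800 samples) for the count chain and leakage audits; five seeds of the
default conditions for the augmentation-benefit comparison; reduced
cohorts (12–24 subjects, 25–30-token samples) where only mechanics are
under test. These sizes were chosen as the smallest that exercise every
code path at the study's true structure.

## Known limitations

* The generator plants lexical-rate effects only; no syntax, semantics,
  or acoustic correlates. Conclusions about real MCI speech require real
  corpora behind the same interfaces.
* The shipped backend is a linear bag-of-words model; it understates what
  a fine-tuned encoder can extract, and its grid knobs, while live, are
  analogues.
* Sample-level evaluation numbers are systematically optimistic — that is
  the point of the leakage audit — and should never be reported without
  the origin-level counterpart.
* Stopword and synonym resources are interfaces with fixtures; the
  package neither ships nor reconstructs any third-party curated list.
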