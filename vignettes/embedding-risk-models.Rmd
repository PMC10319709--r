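---
title: "Free-text embeddings in colorectal-cancer risk prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-text embeddings in colorectal-cancer risk prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

General-practice records hold two kinds of information about a patient:
structured ICPC codes (symptoms and diagnoses recorded at consultations)
and short free-text notes. Established colorectal-cancer (CRC) risk
models use only structured features. This package implements and
evaluates the hypothesis that the free text adds predictive value, by
comparing three logistic models on consultation-level primary-care data:

* **Tab** — age (normalised), gender (three categories, one-hot) and the
  normalised counts of eleven symptom ICPC codes
  (D12, D11, D18, D01, D25, D16, T08, T03, B80, B82, K94: constipation,
  diarrhoea, changed bowel habit, abdominal pain, bloating, rectal blood
  loss, weight loss, appetite loss, two anaemia codes, thrombophlebitis);
* **Txt** — a d-dimensional patient vector `Text_p`, the mean of the word
  embeddings of every token in the patient's notes ("embed and
  aggregate");
* **TabTxt** — the concatenation of both blocks.

All three are plain logistic regressions; the output is
`sigma(w . x + b)`, a probability of CRC.

## Cohort construction

A patient is a **case** if any consultation carries a code whose first
three characters are `D75` (colon/rectum malignancy); the anchor date is
the earliest such consultation. Controls are anchored at their last
visit. The observation window is the two years of data ending five
months before the anchor — the gap guards against suspicion bias, since
consultations shortly before the diagnosis already reflect the workup.
Patients enter the analysis only if they are over 30 at the anchor and
their window holds any tracked data (a non-empty cleaned note or a
tracked ICPC code).

Calendar arithmetic uses fixed-length units throughout: one month = 30
days, one year = 365 days, so the gap is 150 days and the window
`[anchor - 880, anchor - 150)` days, half-open on the right. Fixed units
make the window boundaries exactly reproducible and testable; no
published calendar rule exists for these quantities. Age is computed at
the anchor — the only patient-specific time point both classes share.

Notes are minimally cleaned: every character outside
`a-z A-Z 0-9 + - / \` becomes a space (the minus is ASCII hyphen-minus;
clinical text is ASCII), space runs collapse, the result is lowercased,
and tokenization is split-on-space. The rule is applied character-wise:
deleting whole "rare tokens" would also delete ordinary punctuated words
and could not reproduce worked examples of cleaned notes.

Included patients are split 60/20/20 into training, validation and test
sets, stratified by label: within each class the allocation is exact up
to integer rounding, so prevalence matches across parts within one
patient.

## Word embeddings

Embeddings are learned **offline** — before and independent of the
prediction task — with skip-gram negative sampling (SGNS), implemented
from scratch (C++ core):

* Corpus: cleaned window notes of training-split patients **plus** the
  notes of under-30 patients (excluded from prediction, so they add
  corpus without leaking labels). Validation and test notes never enter
  embedding training; a test asserts a token unique to a test note is
  absent from the vocabulary.
* One bigram pass first: adjacent pair (a, b) is merged into `a_b`
  wherever `(count(ab) - delta) * N / (count(a) * count(b)) > threshold`
  (defaults delta = 5, threshold = 10); merging is a greedy,
  non-overlapping left-to-right pass. Bigrams are detected before
  subsampling so phrase counts reflect the raw corpus.
* Vocabulary: tokens with count >= 3 (low, to keep rare misspelling
  variants); counts and the corpus size N are taken before filtering, so
  `f(w) = count(w)/N` is a raw corpus frequency.
* Subsampling: each occurrence of token w is kept with probability
  `min(1, sqrt(t/f(w)))`, default t = 1e-5. The source method's
  description states both 1e-4 and 1e-5 for this threshold; the package
  binds the explicitly quoted strategy value 1e-5 as the default and
  exposes the parameter, accepting either. Subsampling removes tokens
  before windowing, shrinking effective context distances.
* Training: for each retained center w and context c within a dynamic
  window (radius uniform on 1..5), one SGD step on
  `L = -log sigma(W_w . C_c) - sum_{i=1..5} log sigma(-W_w . C_{n_i})`,
  negatives drawn from the unigram^(3/4) distribution (the standard
  choice of the method this instantiates; the source does not state it).
  Default d = 300 (d = 50 or less in the desk-scale analyses, where the
  corpus is orders of magnitude smaller than a population EMR corpus),
  5 epochs, learning rate decaying linearly 0.025 -> 1e-4. Epoch count
  and rate are not published for the original; these defaults are
  configurable. Training is single-threaded with one deterministic RNG
  stream, so a seed fixes the result bit-for-bit.

The per-pair loss and its analytic gradient are exported
(`sgns_pair_loss()`, `sgns_pair_grad()`) and pinned against central
finite differences in the tests; structural quality is checked by
planted two-block co-occurrence corpora (within-block cosine must exceed
between-block cosine).

## Patient representation

`Text_p` is the elementwise mean (max, min and sum are available; mean
is the default, selected on validation data in the original protocol) of
the target vectors of all in-vocabulary tokens pooled across the
window's notes. Out-of-vocabulary tokens are skipped; a patient with no
in-vocabulary token keeps a zero vector rather than being excluded —
exclusion would silently change the cohort between the Tab and Txt
models and break the paired comparison.

The tabular block is age, the gender one-hot (female, male, other — the
fixed order of the encoding), and the 11 code counts (prefix match on
the first three characters; duplicated codes count multiply, as no
dedup rule is published). Age and the counts are z-scored with
training-split statistics (min-max scaling is available by config); a
feature with zero training spread maps to 0 with a warning.

Before model fitting the text block is, by default, centred and scaled
per dimension with training-split statistics. This is numerical
preconditioning, not a modelling change: logistic regression on an
affinely transformed input spans exactly the same set of predictive
functions, but trained word vectors share a large common component
(a well-known anisotropy of SGNS spaces), and removing it lets
first-order optimisers reach the optimum within the epoch budget instead
of crawling along an ill-conditioned valley. The option is exposed
(`standardize_text`) and the package's tests verify the trainer against
an IRLS fit, which is affine-invariant.

## Model training

Each model minimises mean binary cross-entropy with Adam
(lr 1e-3 by default at the function level, beta = (0.9, 0.999)), over
shuffled mini-batches of 64, for at most 300 epochs, with early stopping
on validation loss and restoration of the best-epoch weights.
Early-stopping patience is not published; the function default is 10
epochs. The pipeline-level defaults use lr 1e-2 and patience 30: at
desk scale the validation loss of a 0.9%-prevalence outcome improves in
tiny, noisy increments, and with the published cap of 300 epochs a
conservative step size under a tight patience stops long before the
text block is learned. Both remain configurable; embeddings are frozen
throughout (a test asserts the matrix is bit-identical before and after
model training). No L2 penalty is applied by default (none is
published); a ridge term is available for stability on d = 300 inputs.

## Evaluation protocol

All evaluation happens on the untouched test set, with 1000 bootstrap
resamples (with replacement, size = test n). Within a replicate the same
index vector is applied to every model, so model differences are paired.
Reported per metric: the bootstrap median and the 2.5th/97.5th
percentiles. Metrics:

* **AUROC** — Mann–Whitney formulation, ties at 1/2.
* **AUPRC** — step-wise precision-at-recall rule (average precision);
  linear interpolation in PR space is biased, and fixing the rule makes
  cross-implementation comparisons exact.
* **Specificity at sensitivity >= 0.95** — the largest threshold whose
  sensitivity still meets the floor (equivalently, the
  specificity-maximising threshold under the constraint). The threshold
  is recomputed inside every bootstrap replicate: the published wide
  specificity intervals are only explicable if the threshold varies per
  replicate, and recomputing reproduces that uncertainty structure.
* **Brier score** `mean((p - y)^2)` and **Brier skill**
  `1 - B/B_ref` against two non-informative references: the
  constant-prevalence predictor (p(x) = 0.0089 at the emulated
  population's prevalence) and the constant-zero predictor.
* **Calibration** — LOWESS smoothing of outcome against prediction
  (span 0.6 by default; none is published). The smoother runs without
  robustness iterations: iterative reweighting treats the rare positive
  outcomes of a binary label as outliers and biases the curve toward
  zero. Values are clipped to [0, 1], with the
  empirical 99th percentile of predictions marked: above it, rare-event
  predictions are too sparse to calibrate.
* **Model comparison** — the percentile interval of per-replicate AUROC
  differences; a difference is significant at p < 0.05 when 0 lies
  outside the 2.5th–97.5th percentile interval.

Replicates that draw a single class are redrawn (not skipped), keeping
the number of replicates fixed; redraws are logged. PR decision-dot
annotations use raw model probabilities (whether the original used
recalibrated ones is unstated).

## The synthetic cohort generator

Real consultation-level EMR data of this kind is confidential, so the
package ships a seeded generator that emulates the statistical structure
the analysis assumes, not the language:

* ~0.89% CRC prevalence (every patient is a case independently with the
  configured probability; cases carry exactly one D75 code at the anchor
  — which keeps the "first D75" labelling rule meaningful — and the
  labeller is additionally tested on fixtures with repeated D75 codes);
* note lengths 1–15 words with mode 7 at mass 0.120 (a discretized
  gamma(5.3, 0.6)), ~10% empty notes;
* a Zipfian background vocabulary (exponent 1.05 over 2000 types by
  default), reproducing the frequent/rare imbalance that subsampling
  exists to handle;
* 20 dedicated signal tokens holding 4% of token mass at baseline; inside
  a case's observation window each token emission is a signal token with
  odds multiplied by `signal_strength` (default 6). Some window signal
  tokens are followed by a fixed partner (30%), planting learnable
  bigrams; 2% of tokens get an adjacent-character swap, emulating typing
  noise;
* the 11 tracked ICPC codes hold 15% of code mass at baseline
  (~0.6 codes per consultation); inside case windows their rate is
  multiplied by `icpc_effect` (default 2.5), leaving background codes
  untouched, so the multiplier acts on the tracked rate exactly;
* age mixtures by case status and per-status consultation counts
  (negative binomial, means 59/76, sd 69/90) follow the published
  baseline table of the emulated population; registration periods span
  4–20 years so every anchor has a fully populated window.

With `signal_strength = 1` and `icpc_effect = 1` the generator plants no
signal, which grounds the leakage tests. What the generator does **not**
emulate: Dutch morphology and syntax, temporal trends within the window,
correlated comorbidity structure, informative visit timing. Passing
recovery tests therefore demonstrates that the pipeline can extract
planted distributional signal without leakage — not that the models
would reach any particular performance on real clinical text.

## Desk-scale study conditions

The shipped analyses and tests run on one CPU in minutes, at sizes
chosen once:

* the signal-recovery run uses 20,000 patients with embedding d = 50 and
  prevalence 0.03, so the absolute case count (~600) matches the scale
  of the emulated population's 541 cases; with the emulated prevalence
  the desk-scale cohort would hold ~30 test cases and the paired
  difference test would be hopelessly underpowered for any effect of
  plausible size;
* the no-leakage run uses 10,000 patients at prevalence 0.20 with the
  case/control differences in age mixture and gender switched off
  (they are genuine signal, not leakage); at the emulated prevalence the
  null AUROC's sampling deviation (~0.07) would dwarf the +-0.05 band
  the test asserts, making the guard vacuous;
* the non-informative-baseline Brier check simulates the emulated
  population's own geometry: 12,128 outcomes (20% of 60,641) at
  prevalence 0.0089.

## Known limitations

* The generator's planted signal is stationary within the window; no
  dose–response as diagnosis approaches.
* SGNS anisotropy (the shared vector component) is reproduced, not
  corrected; the text standardization step compensates at the model, not
  the embedding, level.
* The bootstrap covers test-set variability only; train/validation/test
  re-splits are out of scope, as in the original protocol.
* `other` gender is a fixed three-category contract; real registries
  differ in how a third category is recorded.
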