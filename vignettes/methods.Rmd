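---
title: "Methods: classifying neuropsychiatric symptoms in clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying neuropsychiatric symptoms in clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsehr)
```

## The problem

Neuropsychiatric symptoms (NPS) — apathy, depression, anxiety, agitation,
hallucinations and related behavioural changes — are common in the early
clinical stages of Alzheimer's disease, but memory clinics mostly record
them as free text in electronic health records (EHRs) rather than as
structured data. `npsehr` implements a document-classification pipeline
that detects 13 NPS categories (the 12 Neuropsychiatric Inventory (NPI)
domains plus a "general NPS" category) in clustered clinical notes,
estimates cohort prevalence corrected for classifier error, and compares
note-derived NPS against caregiver-reported NPI scores.

Because real memory clinic EHRs are protected, the package ships a
synthetic corpus generator with fully known ground truth. Every downstream
stage — annotation I/O, preprocessing, classification, prevalence
correction, agreement — is exercised and tested against that generator.

## The model

For each category $c$, a binary elastic-net logistic classifier is fit on
unigram/bigram count features $x$:

$$\min_{\beta_0, \beta}\; \frac{1}{n}\sum_i \log\!\left(1 + e^{-\tilde
y_i(\beta_0 + x_i^\top\beta)}\right) + \lambda\left[\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2\right]$$

with unpenalized intercept and internal standardization (fitting is
delegated to **glmnet**; everything around it — grids, folds, scoring,
selection — is implemented and tested here). Hyperparameters are chosen by
stratified tenfold cross-validation, maximizing out-of-fold AUC over
$\alpha \in \{0.1, 0.55, 1.0\}$ and, per $\alpha$, a 10-point log grid of
$\lambda$ from the smallest all-zero penalty $\lambda_{max}$ down by a
factor $10^{-4}$. The one-standard-error rule is deliberately not used:
selection is by the same statistic the pipeline reports.

The operating cutoff maximizes the Youden index $J(c) =
\text{sensitivity}(c) + \text{specificity}(c) - 1$ over midpoints between
adjacent distinct scores, ties broken toward the smallest cutoff. Cutoffs
are selected on *out-of-fold* scores, not refit scores, so the reported
operating point is not optimistic; external validation applies the frozen
model and frozen cutoff with no re-selection, and a vocabulary hash refuses
silently misaligned feature spaces.

Classifiers whose external AUC falls below 0.80 are excluded ("gated")
from prevalence and EHR-vs-NPI reporting but retained in the evaluation
tables. Categories with fewer than ten positive training documents are
refused outright — ten stratified folds each need a positive example, and
operating characteristics estimated from a handful of positives are
meaningless.

## Prevalence correction

An imperfect classifier observes the apparent prevalence $p = Se\,\pi +
(1-Sp)(1-\pi)$. The Rogan–Gladen estimator inverts this:

$$\hat\pi = \frac{p + Sp - 1}{Se + Sp - 1},$$

defined only when $Se + Sp > 1$. The raw estimate may leave $[0,1]$ when
the observed rate is incompatible with the assumed error rates; the package
reports the raw value, a clamped display value, and a warning — that
pattern (e.g. a clamped 100% with an interval reaching above 100%) is a
diagnostic for a classifier whose external specificity is too low, not a
bug.

The exact interval construction behind the original analysis could not be
pinned from its citation, so the package takes a position and validates it
by simulation: an adjusted-Wald interval — Agresti–Coull centring of the
apparent prevalence ($\tilde p = (x + z^2/2)/(n + z^2)$) — with
delta-method propagation of the sensitivity/specificity sampling
uncertainty from their validation-set confusion counts:

$$\widehat{\text{Var}}(\hat\pi) = \frac{1}{J^2}\left[\frac{\tilde p(1-\tilde
p)}{n+z^2} + \hat\pi^2\frac{Se(1-Se)}{n_{Se}} +
(1-\hat\pi)^2\frac{Sp(1-Sp)}{n_{Sp}}\right], \quad J = Se + Sp - 1.$$

When the validation counts imply perfect rates the sensitivity/specificity
terms vanish and the interval reduces exactly to an Agresti–Coull binomial
interval. Monte-Carlo calibration at $\pi = 0.4$, $Se = 0.85$, $Sp =
0.81$, $n = 3000$, validation $n = 250$ gives 95.5% empirical coverage
(asserted in `[0.93, 0.97]` by the acceptance suite). Intervals are not
clamped by default, so upper bounds above 100% are visible; a `clamp` flag
is available.

A related property the tests assert: the corrected estimate is closer to
the truth than the raw observed rate in at least 90% of replicates with
$Se, Sp \in [0.7, 0.95]$. That claim belongs to the regime where
misclassification bias dominates sampling noise; empirically the win rate
crosses 90% near $n \approx 3000$ (the scale of the larger cohort), and
the test pins it at $n = 10^4$ where the regime is unambiguous.

## Preprocessing choices

The pipeline is tokenize → negation-phrase removal → stop-word removal →
stemming → unigram/bigram extraction → counting. The ordering is a design
choice (the source procedure names the steps but not their order): negation
removal runs first so cue lists match surface forms before stemming mangles
them. Negation handling is cue-plus-window removal (default cues "no",
"not", "denies", "without", "never"; window 3 tokens, truncated at sentence
boundaries) — deliberately not full bidirectional scope detection, which is
out of scope. Bigrams never span sentence boundaries, avoiding nonsense
junctions across note sections. Features are raw counts (a binary-presence
mode exists); the vocabulary is pruned at document frequency 2 to drop
hapax noise, and the pruning is computed on the training corpus only — an
external corpus is featurized against the frozen training vocabulary with
out-of-vocabulary features dropped, so no information leaks backwards.

The stemmer is a self-contained implementation of the classic Porter
algorithm (`"porter"`), validated against the reference snowball
implementation on a frozen word list; `"identity"` disables stemming.
Language-specific resources (the original analysis used Dutch stop words
and a Dutch stemmer) are pluggable but not shipped: the stop-word list and
negation cues are plain configuration vectors.

## The synthetic world

`synthetic_config()` states the world once; its defaults are the conditions
the pipeline is meant to emulate:

* **Prevalences** follow the adjusted note-derived estimates reported for a
  large memory clinic cohort — apathy 0.694, anxiety 0.537, aberrant motor
  behavior 0.475, irritability 0.426, depression 0.385 — with euphoria at
  0.01 (about 5 positive documents in a 500-document training set, the
  observed untrainable case) and plausible mid-range values for the
  remaining categories.
* **Documents** are one note cluster per patient: a handful of boilerplate
  clinical sentences plus background tokens drawn from a synthetic
  vocabulary (`w0001`…), with note dates spread over at most 90 days (the
  three-month diagnostic window). Background and cue vocabularies are
  disjoint by construction, so the cue/background separation is a
  controlled dial, not an accident.
* **Gold-positive** documents always contain at least one non-negated cue
  phrase for the category; **gold-negative** documents may contain a
  negated cue ("no " + cue) at `negation_rate` (default 0.15) and never a
  bare cue. `cue_insertion = FALSE` produces null corpora whose text
  carries no label signal, used for chance-level calibration.
* **Annotators** are two conditionally independent raters flipping each
  document-category gold label with rates $1 - Se_r$ and $1 - Sp_r$
  (defaults 0.90/0.97 and 0.88/0.96, consistent with the high
  inter-annotator accuracies reported for the real annotation effort).
  Noise acts at document-category level, matching how every downstream
  agreement statistic is computed.
* **NPI assessments** score each of the 12 domains positive with
  probability 0.45 given a gold-positive note cluster and 0.05 otherwise
  (positive scores uniform on 1–12, NPI-Q-like), and are available for 67%
  of patients — reproducing both the partial NPI coverage and the
  substantial note-over-questionnaire excess reporting seen in practice.

All randomness descends from one configured seed through fixed 32-bit
child offsets, so each generator is independently callable yet the whole
run is byte-reproducible.

What a green test does **not** establish: the generator's language is a
token soup with planted phrases — no Dutch, no clinical syntax, no
section structure, no correlation between categories within a patient (a
correlation hook is deliberately left unimplemented), and no span-level
annotator disagreement. Classifier AUCs near 1.0 on the strong-signal
world say the pipeline is correct, not that real notes are that easy.

## Numerical and degenerate-input conventions

* Cohen's kappa with both raters constant and identical is defined as 1;
  with $p_o = p_e$ (one rater constant) it is 0. These conventions matter
  because near-degenerate marginals occur in real tables (reported kappas
  of −0.04 and 0.01).
* Discordance proportions with zero denominators are `NA`, never 0.
* AUC follows the Mann–Whitney form with ties counted half; it is exactly
  the brute-force pair count, asserted on random instances.
* brat offsets are 0-based, end-exclusive, in Unicode code points; every
  parse re-verifies the surface string. Discontinuous spans collapse to
  their covering interval (immaterial after document-level reduction).
  Only text-bound annotations are honoured; other line types warn.
* Group comparisons use the uncorrected two-proportion chi-square,
  switching to Fisher's exact test when any expected cell is below 5;
  Benjamini–Hochberg adjustment spans the categories of one comparison.
* Elastic-net fits converge to coefficient tolerance $10^{-9}$ for single
  fits (matching an unpenalized `glm` to $10^{-4}$ at $\lambda = 0$); the
  cross-validation grid uses the standard $10^{-7}$, which changes selected
  models by less than fold noise and is an order of magnitude faster on
  null-signal corpora.

## Known limitations

Negation handling misses pre-negated scopes ("symptoms were absent");
category correlation within patients is not modelled; probability
calibration is out of scope (only ranking and the Youden operating point
are used); agreement is document-level only — span-overlap agreement is
deliberately not implemented; and the prevalence machinery assumes the
validation-set confusion counts are exchangeable with deployment error
rates, which the external-validation gate enforces only down to AUC 0.80.
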