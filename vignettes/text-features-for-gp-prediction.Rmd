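---
title: "Text features for patient-level prediction from GP records: methods and design"
author: "notepredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Text features for patient-level prediction from GP records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

General-practitioner EHR databases hold two kinds of predictive information:
structured events (coded conditions, prescriptions, measurements, procedures)
and free-text notes. `notepredict` implements a complete benchmark for
quantifying what the text adds: it featurizes both sources for a
patient-level prognostic prediction task, trains three standard learners on
seven feature-set combinations, and validates every model both internally
(held-out patients from the same EHR system) and externally (all patients of
a second EHR system).

A prediction task is defined by a target event (whose occurrences become
index dates), an outcome event sought in a time-at-risk (TAR) window after
the index, and an observation window before it. Throughout the package:

* the observation (covariate) window is the closed interval
  [index − 365 days, index − 1]; the index date itself never contributes a
  covariate, which prevents outcome leakage at the index;
* the TAR is the closed interval [index + `tar_start_days`,
  index + `tar_end_days`];
* observations with fewer than 365 days of observation before the index, or
  whose observation period ends before the end of the TAR (loss to
  follow-up), are excluded;
* only the readmission-style task allows multiple observations per patient;
  all splitting is at the subject level so one patient never straddles
  train and test.

## Feature sets

Five member sets are built per observation and combined into seven
combinations (S = D+E; T = D plus one text representation; S+T = D+E plus
one text representation — demographics are in every combination because
they are always available):

* **D** — age in calendar years at the index date and sex.
* **E** — one binary indicator per (domain, concept code, window) for the
  365-day and 30-day look-back windows; occurrence, not counts. Columns
  all-zero in the data at hand are dropped, so the feature space is the set
  of observed (code, window) pairs; held-out and external data are
  projected onto the training space (novel codes dropped, absent ones
  zero-filled).
* **Tterm / Ttfidf** — bag-of-words over one document per observation (all
  note text in the 365-day window concatenated). Preprocessing replaces
  digits, newlines and underscores with spaces; tokenization lowercases
  and splits at spaces and punctuation. Document frequencies are computed
  on the training corpus and terms occurring in more than 80% or fewer
  than 0.1% of documents are removed; both bounds are read strictly, so a
  term with df exactly 0.8N is kept. Tterm is the binary occurrence
  indicator; Ttfidf is tf × ln(N/df) with raw counts, natural log, no
  smoothing and no normalization — the plain textbook form, recorded in
  the serialized pipeline so variants remain switchable. The vocabulary
  and idf table are fitted on the training partition only and applied
  frozen everywhere else; this is both the leakage guard and the
  definition of external-validation transfer (unseen external terms are
  dropped).
* **Tcon** — dictionary-based clinical concept extraction with
  ConText-style modifier detection. Sentences are split at terminal
  punctuation and at newlines (GP notes are line-oriented shorthand with a
  median sentence length of about five words). Matching is
  case-insensitive, leftmost-longest and non-overlapping, with multi-word
  terms matched as contiguous token sequences. Trigger rules assign
  negated / hypothetical / historical / experiencer-other flags over a
  directional scope of at most 10 tokens within the sentence, truncated at
  scope terminators; a trigger whose span overlaps a concept mention is
  ignored (the concept wins). By default a concept counts as present if it
  has at least one mention that is not negated, not hypothetical and not
  about another person; historical mentions are kept. This filter is a
  design choice (the feature semantics of the modifiers are genuinely
  open) and is configurable via the `disqualify` argument. The bundled
  lexicon is a small synthetic Dutch toy vocabulary and the trigger table
  is a compact (~45 entries) Dutch rule set; both are plain CSV and
  user-replaceable, since licensed Dutch SNOMED/UMLS distributions cannot
  be shipped.

## Learners and tuning

Three learners are used: L1-regularized logistic regression (glmnet),
gradient boosted trees (xgboost) and random forests (ranger). Grids are
deliberately small and conventional: C ∈ {0.001, 0.01, 0.1, 1, 10} for the
lasso; depth {2, 4, 6} × rounds {50, 200} × learning rate {0.05, 0.2} for
boosting; 200 trees with mtry ∈ {√p, 0.3p} for the forest. Selection is by
mean AUROC over 3-fold cross-validation; folds are subject-level, for
consistency with the outer split. Ties resolve toward the earlier grid
entry, which is ordered most-regularized/smallest-model first. One global
seed governs the outer split, the folds and all learner randomness, and is
recorded in every output record.

## Evaluation

`computeMetrics` implements AUROC in the rank (Mann–Whitney) form with
midrank tie handling, AUPRC as the area under the precision–recall step
function (average precision, not trapezoidal interpolation — it is exactly
reproducible by a threshold sweep), the Brier score, and
precision/recall/F1 at the F1-maximizing threshold found by exhaustive scan
over the unique predicted probabilities (ties toward the higher threshold).
Family comparisons (S vs T vs S+T) use two-sided unpaired Wilcoxon rank-sum
tests — exact enumeration when both groups have ≤ 10 untied values, normal
approximation with tie correction otherwise — Bonferroni-adjusted over the
pairs tested within one (task, validation type, metric) analysis. The
unpaired flavor is a design choice: the compared groups are different
models, not paired measurements. Predictive multiplicity is the Pearson
correlation of predicted probabilities between family pairs sharing the
algorithm (and the text representation where applicable), averaged across
representation × algorithm cells, with qualitative bands at r = .4/.6/.8.
A model that predicts a constant (e.g. an intercept-only lasso selected by
cross-validation on an uninformative feature set) has undefined correlation
with anything; such pairs are dropped from the average rather than coerced
to a number.
Feature importance is |β| for the lasso (signed values reported), impurity
decrease for the forest, and gain for boosting, always carrying the
source-set provenance of each feature.

## The synthetic data generator

No GP database can be shipped, so the package carries a seeded generator
that emulates the statistics that matter for this pipeline, at desk scale:

* notes are bags of Zipf-distributed Dutch-like tokens (~2000 types)
  arranged into short sentences with no grammar — sufficient to exercise
  tokenization, document-frequency pruning, TF-IDF and dictionary matching,
  and deliberately nothing more;
* per-observation volumes mirror a real GP setting: about 35 notes and
  ~420 words per 365-day observation for system A, 45 notes for system B,
  and per-domain event medians (condition 14, drug 7, measurement 20,
  procedure 1); default populations are 700 patients (A) and 450 (B),
  chosen once as a desk-scale working size;
* outcome labels are drawn from a logistic model over planted signal
  indicators: selected text tokens inserted into notes and selected event
  codes inserted into histories, each present with probability 0.3 and
  carrying a configurable log-odds weight; task baselines put outcome
  prevalence in the 0.04–0.46 range typical of GP prediction problems;
* a second EHR system is emulated by renaming a fraction (default 30%) of
  the background vocabulary and changing the volume profile; planted
  signal terms are exempt from renaming, so the signal is transferable and
  external validation measures representation transfer, not signal loss;
* observation periods are generated so that a controlled fraction (~8%
  each) of patients violates the prior-observation rule or drops out
  during the TAR, keeping the cohort exclusion logic under test;
* everything is a pure function of the seed: the same seed yields
  byte-identical tables.

What the generator does **not** emulate: grammar and word order (irrelevant
to bag-of-words and dictionary matching), realistic longitudinal disease
trajectories, correlated comorbidity structure, misspellings and
abbreviation noise, and class-dependent note length. Green tests therefore
show that the pipeline is computed correctly and that true signal of the
planted form is recovered and transfers across systems; they do not show
that any particular clinical performance level would be reached on real
data.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar dates; all windows are closed intervals in
  whole days.
* Age is a single numeric column (calendar-year difference), not binned;
  binning can be layered on by the user.
* An observation with no notes in the window yields an empty document and
  an all-zero text-feature row — it is kept, not dropped.
* For corpora smaller than 1/min_df documents the lower pruning bound
  removes nothing (the threshold is below one document).
* A term present in every fitting document has idf ln(1) = 0 and scores 0
  everywhere, also on held-out documents.
* Single-class training labels raise an error; single-class validation
  labels make that cell's metrics NA with a warning rather than aborting
  the grid.
* Empty cohorts warn and return zero rows (a configuration may simply not
  match a dataset).
* Matrix persistence is MatrixMarket plus a JSON descriptor sidecar;
  values round-trip at full double precision, and a missing sidecar or
  dimension mismatch is an integrity error. Serialized text pipelines
  carry an FNV-1a vocabulary hash; a mismatch on load warns about
  tampering or corruption.

## Study sizes used by the shipped test suites

The bundled benchmark runs the full 4-task, 7-combination, 3-algorithm grid
(84 models, each validated internally and externally) on the default
two-system populations of 700 and 450 patients. The stochastic
signal-recovery study uses 10 seeds at 400 patients with the lasso as the
representative learner across all seven combinations; the lasso is the
cheapest of the three learners and its importance values (betas) are the
ones inspected for planted-term recovery. These sizes are the package's
choice of a reproducible desk-scale experiment; all of them are ordinary
function arguments, so larger studies are one call away.

## Known limitations

* The toy lexicon has ~35 entries; real concept extraction uses
  vocabularies five orders of magnitude larger, where matching speed and
  ambiguity handling become first-order concerns.
* The ConText scope model (same sentence, ≤ 10 tokens, global terminators)
  is the classic default; per-category terminators and pseudo-triggers are
  not implemented.
* TF-IDF variants (sublinear tf, smoothed idf, normalization) are not
  implemented, only recorded as the pipeline's representation field.
* Hyperparameter grids are small by design; the harness accepts arbitrary
  grids via `modelSpec`/`runExperiment` arguments.
* No calibration analysis beyond the Brier score, and no post-hoc
  explanation methods (LIME/Shapley) — importance is reported per learner
  as described above.
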