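---
title: "Answer-pattern screening for rare diseases: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Answer-pattern screening for rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rdscreen)
```

## The screening model

`rdscreen` treats rare-disease screening as *answer-pattern recognition*:
instead of matching clinical symptoms to diseases, it asks whether the way
a patient describes their pre-diagnostic experience — on 53 ordinal items
scored 1 ("completely false") to 4 ("completely true") — resembles the way
rare-disease patients in general describe theirs. The modelling pipeline
has four layers:

1. **Encoding.** A complete questionnaire becomes a 55-element vector: the
   53 answers verbatim, a gender code, and age in years. Answers are used
   as numeric 1–4 values; no scoring key, reverse coding or scaling is
   applied at this stage.
2. **Pairwise subsets.** The disease landscape is too heterogeneous for a
   single four-class model, so training is decomposed into three pairwise
   challenges, each contrasting a clinically coherent rare-disease
   composite with one comparison group (other non-rare diseases, chronic
   diseases, psychosomatic disorders), with class sizes 90:90, 90:90 and
   42:38. Each questionnaire belongs to at most one subset; assembly is
   seeded uniform sampling from the eligible pool, with provenance logged.
3. **Base classifiers.** Four binary models per subset: a degree-3
   polynomial-kernel SVM, a random forest, logistic regression, and linear
   discriminant analysis. Each emits a coded diagnosis and the probability
   of its predicted class.
4. **Fusion.** The four (index, probability) pairs form an 8-element
   meta-feature on which a further SVM — the fusion classifier — is
   trained. Its job is to resolve "diagnostic parity", the 2-vs-2 (or
   otherwise ambiguous) splits among the base votes, and it is the model
   whose probability is reported to the user.

The per-patient output is a triple of fused rare-disease probabilities,
one per subset, with the complement in each pair implied. The suggestion
rule is alarm-oriented: if any of the three probabilities reaches 0.5 the
tool points to a rare disease in the argmax subset; otherwise it suggests
the comparison group whose complement probability is largest. Exact ties
at 0.5 resolve towards the rare-disease side — a deliberate asymmetry,
since the cost of silencing a true rare-disease alarm exceeds the cost of
one more false alert.

## Anti-leakage stacking

How the fusion stage is trained relative to cross-validation folds is the
single most consequential open design choice in this architecture. If the
meta-classifier is trained on the base models' *resubstitution* outputs,
it learns from probabilities that are optimistically sharp, and reported
fusion performance inflates. `rdscreen` therefore uses out-of-fold
stacking: within each training set the data are split into `k_inner = 5`
stratified folds, base models trained on four folds predict the fifth, and
only those held-out predictions train the fusion SVM; the final base
bundle is then refit on all training data. The provenance of every inner
fold is logged and `assert_no_leakage()` checks that no record both
trained a base model and contributed a stacking feature in the same fold.
`k_inner = 5` keeps roughly 64 of the 80 records of the smallest subset in
each inner training split — enough for all four families to fit stably.
A resubstitution-trained fusion stage could report higher numbers; that
difference is a property of the evaluation protocol, not of the data.

## Parameters that matter

* **Hyperparameters** are pinned in `training_config()` rather than
  inherited silently from libraries: SVM cost 1, kernel offset 0, degree 3;
  200 random-forest trees (out-of-bag error is flat well before 200 at 55
  predictors); plain maximum-likelihood logistic regression. Degree 3 for
  both base and fusion SVMs is part of the method definition.
* **Standardization** (per-feature centering/scaling fitted on the
  training split) is ON by default for the SVM, logistic and LDA fits:
  age spans 0–120 while answers span 1–4, and without scaling age dominates
  every kernel distance. The random forest sees raw features; trees are
  scale-invariant. The fitted state is stored in the model bundle and
  re-applied at predict time.
* **Gender coding** is female = 0, male = 1 by default and configurable;
  any fixed binary coding is equivalent for these model families, but the
  choice must be explicit so that encode/decode round-trips exactly.
* **Probability calibration.** Margin methods do not natively output
  probabilities; the SVMs use the fitted sigmoid (Platt-style) probability
  model of `e1071`, fitted within the training split, so that base and
  fusion probabilities are comparable inputs for stacking.

## Numerical and degenerate-input choices

* **Truncated reporting.** Reported percentages are truncated, not
  rounded, to one decimal (79/90 = 87.78% reports as 87.7%); this is the
  only convention under which the three subset sensitivities 87.7, 93.3
  and 85.7 average to the printed 88.9. Full double precision is kept
  internally; `truncate_pct()` applies a 1e-6 guard so that values exactly
  representable at one decimal are not truncated downwards by floating
  error.
* **LDA degeneracy.** On small subsets a feature can be constant within
  classes, making the pooled covariance singular. Predictors whose pooled
  within-class variance falls below `lda_var_tol` are excluded from the
  LDA fit (and recorded in the bundle) — the explicit equivalent of
  ridge-regularizing them away.
* **Separation in logistic regression.** Near-separable subsets produce
  fitted probabilities of 0/1 and rank-deficiency warnings; predictions
  remain valid as scores and are used as such.
* **ROC/AUC.** The ROC curve is built by sweeping thresholds over the
  unique fused probabilities and integrating trapezoidally, which equals
  the Mann–Whitney concordance probability with ties counted half; the
  test suite checks this identity against an exhaustive pair-counting
  oracle.
* **Record-order invariance.** Training rows are canonicalized by record
  id before any fit, so the fitted models — and every output probability —
  are bit-identical under permutations of the input file for a fixed seed.
* **Seeds.** One run seed drives everything; sub-seeds for fold
  assignment, per-fold fits and the fusion fit are derived by a fixed
  integer scheme, so no two stages consume the same stream.

## What the synthetic generator emulates — and what it does not

The generator models each diagnostic group as independent per-item
categorical distributions over {1,2,3,4} — the weakest assumption
compatible with an ordinal scale, making no ordering or correlation claims
the pipeline does not need. Group separation is a single mixture shift of
strength $\delta$ towards "completely true" on an affected-item subset
(default: 20 of 53 items), so the per-item total-variation distance grows
linearly in $\delta$: $\delta = 0$ gives identically distributed groups
(a true null), $\delta = 1$ degenerates affected items at answer 4. Ages
are truncated-normal (mean 40, sd 15, bounds 0–120), gender balanced,
missingness item-wise Bernoulli. The default grid
$\{0, 0.2, 0.4, 0.6\}$ spans chance to near-separable regimes.
`simulate_study_pool()` additionally reproduces the return-rate structure
of a realistic campaign — 1763 questionnaires of which 225 are incomplete,
1155 evaluable across the four analysis groups, diagnosis counts matching
the published return rates except that the cystic-fibrosis count is raised
to 44, because the published per-diagnosis counts cannot otherwise supply
the 90-record rare-disease side of subset 1 (the original study's
reconciliation of this point is unpublished).

What the generator deliberately does **not** model: inter-item correlation
beyond the shared shift, item-specific effect heterogeneity, age/gender
associations with disease group, response styles (acquiescence, extreme
responding), or informative missingness. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers separation that
is present and reports chance when it is absent — they do not certify
real-data performance, where correlated items and weaker, unevenly spread
effects will generally lower sensitivity.

Problem sizes in the test suite follow the study layout (90:90 and 42:38
subsets, 10-fold outer cross-validation, 5-fold inner stacking); null and
separable calibration checks average 20 and 10 generator seeds
respectively, enough to pin the mean sensitivity to a few percentage
points.

## Known limitations

* The original study's subset memberships, software defaults and fold
  assignments are unpublished, so its exact cross-validated numbers are
  not reproducible; the package instead fixes every such choice explicitly
  and validates the pipeline's statistical behaviour (null calibration,
  effect-size recovery, fusion-vs-single-family ordering) on synthetic
  cohorts.
* Spreadsheet ingestion is not provided; the canonical format is the
  UTF-8 CSV documented in `load_records()`. Spreadsheet exports should be
  saved as CSV with the same column contract.
* The fusion stage can only arbitrate among its four base families; it
  cannot rescue a signal that none of them detects.
* Incomplete questionnaires are excluded, never imputed. With
  questionnaire-level missingness this is conservative; under informative
  missingness it could bias the trained models.
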