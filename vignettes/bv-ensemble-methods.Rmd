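---
title: "Predicting incident bacterial vaginosis from the partner's penile microbiome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting incident bacterial vaginosis from the partner's penile microbiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvote)
```

## The problem

Bacterial vaginosis (BV) is defined here by the Nugent Gram-stain score:
0–3 normal, 4–6 intermediate, 7–10 BV. In a longitudinal couples cohort,
*incident* BV means a follow-up Nugent score of 7–10 (at month 1, 6 or 12)
in a woman whose baseline score was 0–6. The question this package
operationalises is whether the male partner's **baseline penile microbiome**
— a sparse, compositional 16S taxa count profile — predicts that incident
outcome, and which taxa carry the signal.

The pipeline has five stages, each exposed as plain functions and tied
together by `run_pipeline()`:

1. **Cohort derivation** (`derive_outcome()`, `build_cohort()`): couples
   with baseline Nugent 7–10 are excluded (prevalent, not incident, BV);
   couples with no attended follow-up cannot contribute incidence and are
   excluded; the remainder are labelled incident (1) or persistently
   negative (0) by the *first* follow-up visit scoring 7–10. A sensitivity
   mode additionally excludes intermediate (4–6) baselines, which may
   represent misclassified or developing BV.
2. **Compositional preprocessing** (`assemble_features()`): taxa
   contributing < 0.01% of the table's total reads are removed (inclusive
   threshold, assessed on raw counts over all samples of a site's table, so
   the rule is idempotent and unaffected by the later pseudo-counts); zero
   counts are replaced by independent Uniform(0.5, 0.95) draws; each sample
   is centered-log-ratio transformed (natural log; the base only rescales
   columns and is absorbed by the next step); each feature is min–max
   normalized to [0, 1] across all samples. Circumcision status is appended
   as a 0/1 feature after normalization.
3. **Rebalancing** (`smote_oversample()`, `undersample_majority()`): with
   roughly 31% incidence the classes are imbalanced, biasing classifiers
   toward the majority class. SMOTE synthesises minority points on segments
   between a minority sample and one of its k = 5 nearest minority
   neighbours (Euclidean distance on the normalized features, which is why
   min–max normalization precedes it); the majority class is then randomly
   undersampled.
4. **Classification and voting** (`bv_ensemble()`): random forest, RBF-kernel
   SVM and KNN are evaluated by stratified 10-fold cross-validation repeated
   many times, with grid-search tuning nested inside every training
   partition, and combined per sample by majority vote (with three binary
   voters no ties are possible). Per repeat, held-out predictions are pooled
   across folds (micro-average) and scored as accuracy, sensitivity,
   specificity and rank-based AUC; point estimates are means over repeats
   and the per-repeat AUC vectors are retained.
5. **Importance and comparison** (`ensemble_importance()`,
   `permutation_t_test()`): per-classifier feature rankings are aggregated
   by rank averaging; AUC distributions from two runs (e.g. two anatomic
   sampling sites) are compared by a permutation t-test.

## Models and estimators

**Ensemble score and AUC.** Each classifier emits a positive-class score in
[0, 1]: the fraction of trees voting positive (random forest), the fraction
of positive nearest neighbours (KNN), and a logistic transform of the signed
decision value (SVM — any monotone transform gives the same AUC, which is
rank-invariant). The voting label is the majority of the three hard labels;
the voting score defaults to the arithmetic mean of the three scores, with a
`vote_fraction` alternative (number of positive votes / 3) retained because
a discrete ensemble score is equally defensible. AUC is the Mann–Whitney
statistic computed from midranks: P(random positive scores above random
negative) + ½·P(tie).

**Rank-averaged importance.** Features are ranked per classifier —
permutation importance (mean out-of-bag accuracy decrease) for the forest,
backward recursive feature elimination by cross-validated accuracy for the
SVM, and leave-one-feature-out accuracy degradation for KNN. The KNN
criterion is a deliberately simple, testable feature-support surrogate: the
literature criterion it stands in for is not specified precisely enough to
reconstruct, so the package implements a defined alternative and labels it
as such. The ensemble ("voting") rank orders features by the mean of the
three ranks; ties are broken by the best (minimum) single-classifier rank
and then by label order. This tie-break is not arbitrary: it is the unique
simple rule that reproduces all three tie orders in the published 20-taxon
meatal ranking bundled with the package (`meatal_rank_table()`), which the
test suite replays end to end.

**Permutation t-test.** Two per-repeat AUC vectors are compared by the Welch
(unequal-variance) t statistic under random relabelling, two-sided, with the
add-one correction p = (1 + #{|t*| ≥ |t|}) / (1 + B) so p is never exactly
zero. Permutations are drawn over the sorted pooled values with the smaller
group sampled, which makes p exactly invariant to swapping the inputs. The
Welch form was chosen because the two AUC distributions being compared
typically come from different cohort sizes with visibly different spread.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis assumes,
so every stage is testable without cohort data:

* outcome ~ Bernoulli(0.31) and circumcision ~ Bernoulli(0.59) per couple —
  the incidence and circumcision prevalence of the cohort design emulated;
* composition ~ Dirichlet(α) per couple, counts ~ Multinomial at a
  log-normal depth. The default α is a power-law profile (total
  concentration 5, weights ∝ rank^−1.5), chosen once to produce the steep
  abundance gradient and 20–99% per-taxon presence range typical of penile
  16S tables; presence is monotone in α, which the tests check over a grid.
* depth: log-normal with meanlog = log(25997) and
  sdlog = log(33779/19524) / (2·Φ⁻¹(0.75)) — the two free parameters solved
  exactly from the target median and IQR;
* planted effects multiply the Dirichlet concentrations of chosen taxa by
  exp(shift) in incident couples, preserving compositional closure — no
  post-hoc count edits;
* Nugent trajectories are minimal: only the 0–3 / 4–6 / 7–10 categories
  matter downstream, so integer scores are drawn uniformly within category;
  incident couples receive one 7–10 score at a random follow-up month with
  earlier follow-ups capped at 6, so `derive_outcome()` recovers the drawn
  outcome exactly. Baselines are intermediate with probability 0.155.

What the generator does **not** emulate: read-level sequencing error,
contaminants, taxon co-occurrence structure, depth–composition correlation,
or longitudinal microbiome dynamics (one baseline sample per couple). A
passing planted-signal test therefore shows the pipeline recovers a clean
Dirichlet-multinomial effect at the stated size — not that it would perform
comparably on real cohorts.

## Numerical and design choices

* **Filtering before imputation**, on the grand total of the site's table:
  imputed pseudo-counts would otherwise perturb the 0.01% rule. The
  threshold is inclusive (≥).
* **Uniform(0.5, 0.95) zero replacement** uses R's half-open uniform; the
  open/closed endpoints differ on a set of measure zero.
* **Constant feature columns** map to 0 under min–max normalization
  (avoiding 0/0; such a column is uninformative either way), and min–max is
  idempotent on its own output.
* **Normalization statistics are computed over all samples** before
  resampling and cross-validation, reproducing the original analysis
  design. This is a mild form of information sharing across folds; the
  stage functions are exposed individually so a strict train-fold-only
  variant can be composed if wanted.
* **Pre-CV SMOTE is the default** (`resample_control(mode = "pre_cv")`),
  again for fidelity to the analysis design this package reproduces:
  the full training set is rebalanced once and cross-validation runs on
  the augmented data. Synthetic minority points then share information with
  their parents across fold boundaries, which inflates absolute performance
  estimates — the known cost of that design. `mode = "within_fold"`
  rebalances only training folds and is what the package's own null
  calibration uses: with zero planted effects the within-fold pipeline's
  mean voting AUC must sit in [0.45, 0.55], a check that would fail by
  construction under pre-CV leakage and would then say nothing about the
  classifiers themselves.
* **SMOTE counts**: `round(percent/100 × n_minority)` synthetic points,
  parents cycled through a shuffled permutation of the minority so the load
  spreads evenly; at 100% each minority point parents exactly one synthetic
  point. `"balanced"` undersampling matches the majority to the augmented
  minority; an explicit integer target is available because published
  before/after counts do not always correspond to a single spread rule.
* **Tuning is nested**: a 5-fold inner cross-validation inside every
  training partition, ties broken by grid order, single-point grids short-
  circuited. The default grids are deliberately compact — random forest at
  the canonical mtry = ⌊√p⌋ with 500 trees (forests are famously
  insensitive to mtry), SVM over cost {1, 10, 100} × γ {1, 2}/p, KNN over
  odd k {3, …, 15} (odd k avoids vote ties) — keeping the fully nested
  scheme tractable at repeated-CV scale; all grids are user-replaceable.
* **Stratified folds** with per-repeat seeds `base_seed + repeat`, so
  repeats are independent but any run is bit-reproducible from its
  manifest. At n ≈ 200 with ~31% positives, unstratified 10-fold splits
  occasionally produce single-class test folds, which would leave per-repeat
  sensitivity and AUC undefined.
* **Problem sizes.** The package default is 50 cross-validation repeats,
  which stabilises the mean AUC to well under a point of its value at
  n ≈ 200; the full-scale analysis design uses 1000 repeats
  (`cv_control(n_repeats = 1000)`). The bundled calibration suites run at
  n = 200 couples, 50 taxa, 50 repeats, with 5 planted taxa at a
  1.5 natural-log concentration shift for the signal-recovery check. The
  null calibration averages the voting AUC over 16 independent zero-effect
  cohorts (4 repeats each): a single cohort's repeat-mean AUC has a
  standard deviation near 0.05 at this n (CV repeats reuse the same
  samples, so they do not average that noise away), while the Monte-Carlo
  mean over cohorts estimates the null expectation to about ±0.01.

## Known limitations

* The pre-CV SMOTE default reproduces a design whose absolute performance
  estimates are optimistic; comparisons *between* runs with the same design
  remain meaningful, which is what the permutation t-test is for.
* Importance is computed once on the full rebalanced training set (as a
  single reported ranking implies), not per CV fold, so rank stability
  across folds is not quantified.
* The permutation t-test treats per-repeat AUCs as exchangeable units; CV
  repeats share the underlying samples, so the test compares AUC
  *distributions*, not independent replicates — p-values should be read
  accordingly.
* Only scheduled visits at months 1, 6 and 12 are modelled; unscheduled
  visits and repeat BV episodes after the first are out of scope.
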