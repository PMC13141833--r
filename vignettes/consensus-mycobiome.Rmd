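---
title: "Consensus differential abundance for sparse tumor mycobiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential abundance for sparse tumor mycobiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycovar)
```

## The problem

Tumor sequencing data contain a small fungal read fraction whose abundance
may vary with patient demographics (sex, age, race, BMI). Two properties of
these data make naive analysis unreliable. First, the counts are sparse,
overdispersed and compositional, and are affected by technical batch
(sequencing center) effects; conclusions can hinge on the choice of
normalization and batch correction, and some normalizations can even
*manufacture* signal in features that contain essentially no reads. Second,
demographics are confounded with each other and with technical batch, so
unadjusted group comparisons are biased.

`mycovar` addresses both problems with a consensus design: a species is
called differentially abundant for a demographic factor only if the
IPTW-weighted regression test is significant under **every** member of a
family of 14 transformation x batch-correction pipelines, and the call is
additionally confirmed by a Mann-Whitney test on the raw, unnormalized
counts.

## The analysis model

For one cancer type and one binary demographic contrast (male vs female,
age >70 vs <=70, a race pair, or BMI >30 vs <=30):

1. **Propensity scores.** Logistic regression of group membership on the
   remaining demographic/clinical covariates — age (continuous), sex, race,
   tumor stage (collapsed to levels 1-4, one-hot), histology (one-hot) —
   *excluding the tested factor itself*. For the BMI contrast the
   confounder set is exactly {age, sex, race}. Fitted probabilities are
   clipped to [0.01, 0.99].
2. **ATE weights.** `1/e` for group 1, `1/(1-e)` for group 0. Balance is
   assessed by weighted standardized differences,
   `100 |m1 - m0| / sqrt((s1^2 + s0^2)/2)`; values above 10% are flagged
   but do not abort the run, since the diagnostic, not an automatic rule,
   is the methodological requirement.
3. **Per-species test.** Weighted least squares of the transformed
   abundance on an intercept and the group indicator; the p-value is the
   two-sided t-test on the group coefficient. With a single predictor this
   equals the model F-test, which is why "the model's p-value" and "the
   coefficient's p-value" coincide here. Model-based standard errors are
   used; a robust-variance variant is a deliberate non-goal because the
   plain weighted fit is the method being packaged.
4. **Multiplicity.** Bonferroni within each (cancer, factor, combination)
   stratum, i.e. `m` = number of species tested; a global-m variant is
   available via `bonferroni_scope = "global"` in the configuration.
5. **Consensus.** Significant in all 14 combinations, then confirmed on raw
   counts with a two-sided Mann-Whitney test (normal approximation with
   tie and continuity correction).
6. **Sensitivity.** The whole analysis is repeated with weights truncated
   at the 99th percentile (linear interpolation on the sorted weights) and
   the symmetric difference of the consensus sets is reported.

## The 14 combinations

Four transformations — CLR (zeros offset to 1; natural log), CLR_C
(multiplicative zero replacement with `delta = 0.5 x` the sample's smallest
nonzero count, total preserved), relative abundance, and a voom-style
matrix (`log2((count + 0.5)/(total + 1) * 1e6)` followed by quantile
normalization) — crossed with four unsupervised corrections: ComBat
(parametric empirical Bayes, no covariates), batch mean centering, an
MMUPHin-like count-level correction, and PLSDA component removal. Two
structural rules reduce the 16 pairs to 14: PLSDA operates on the
unconstrained CLR-family space only, and the count-level correction runs
*before* the transformation while every other correction runs after.

Only unsupervised corrections are included; supervised methods (SNM) can
leak the outcome into the corrected data and are excluded by design.

Numerical and convention choices worth knowing:

* **BMC** subtracts the within-batch mean and restores the per-feature
  grand mean, so pooled feature locations (and hence regression
  coefficients) keep their scale; `restore_grand_mean = FALSE` gives pure
  centering.
* **ComBat** is the canonical parametric EB implementation. Two
  consequences of genuine EB moderation: on *identical* batches locations
  are untouched but per-feature variances are slightly rescaled (it is not
  the exact identity), and after removing a location shift the residual
  batch-mean gap equals the sampling noise of the batch means, which EB
  deliberately does not overfit. Features with zero pooled variance are
  passed through unchanged.
* **The MMUPHin-like correction** is a simplified reimplementation of the
  idea, not a port: per feature, batch offsets of the log nonzero entries
  relative to the across-batch grand mean are shrunk toward zero by an
  empirical-Bayes factor (`tau^2/(tau^2 + se^2)`, with `tau^2` the excess
  spread of offsets across features) and divided out on the natural scale.
  Zeros stay exactly zero; count input is rounded back to integers;
  relative-abundance input is re-normalized.
* **PLSDA removal** deflates the column-centered data by its projection on
  the first `k` PLS components against one-hot batch labels; `k` defaults
  to `min(n_batches - 1, 5)`. Note that deflating one component of a
  p-feature matrix removes about `1/p` of the variance even for labels
  independent of the data; with the default 40-feature cohorts that is a
  ~2.5% perturbation.
* **Quantile normalization** resolves within-sample ties by assigning the
  tie group the mean reference value over its rank span. With ties, the
  post-normalization sorted vectors are therefore *not* exactly identical
  across samples; they are identical on tie-free data.

## The artifact audit

A feature with a raw count of zero in more than 95% of samples cannot
carry real classification signal, yet after rank-based normalization its
values can separate sample classes. The mechanism: all zero-count features
in a sample tie at the bottom of the log-CPM ranking, and the tie group's
assigned value depends on how many zeros the sample has. If two classes
differ in overall sparsity, the zero-tie value becomes class-dependent —
signal manufactured from nothing. The audit provides `zero_fraction_screen`
(strictly-greater-than threshold, default 0.95), `evaluate_threshold`
(strict `>` classifier, PPV and sensitivity in percent) and
`best_threshold` (midpoint scan maximizing PPV subject to a sensitivity
floor, default 25%; ties prefer higher sensitivity, then the lower
threshold). The audit accepts any transformed matrix, so all 14
combinations can be audited, not only the voom-style one.

## Cross-cohort concordance

To compare read counts of the same samples processed by two pipelines, the
package computes per-sample total and per-feature Pearson correlations,
and a depth-insensitive ratio statistic: repeatedly (default 2,000 times)
draw a uniformly random maximal set of disjoint feature pairs (155
features give 77 pairs covering 154), compute `log((c1 + 1)/(c2 + 1))` per
pair and sample, and correlate the pooled ratio vectors between cohorts.
The log and the +1 pseudo-count are our choices (the ratio's zero handling
is otherwise unspecified); they make the pair symmetric and bound the
influence of zeros. Pooling over pairs x samples yields one correlation
per resample; a per-sample-then-average mode is available
(`mode = "per_sample"`). Two resample distributions are compared with a
two-sided Mann-Whitney test. Note the pseudo-count makes exact scale
invariance hold only up to entries where one cohort has a zero; on cohorts
whose shared features are regularly detected (the intended use, mirroring
comparisons restricted to genera common to all cohorts) the effect on the
mean resampled correlation is well below 0.05.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with
known ground truth:

* counts: negative binomial per cell (variance `mu + 0.5 mu^2` by
  default) with an independent Bernoulli dropout mask (default 5% —
  structural sparsity arises mostly from low-abundance features through
  the negative binomial itself);
* library sizes: log-normal, median 3,000 fungal reads per sample
  (sdlog 0.4);
* features: log-normal relative levels; 10% are degenerate near-all-zero
  species (relative level scaled by 1e-3), the raw material of the
  artifact audit;
* batch effects: per (batch, feature) log2 effects, sd 1, centered per
  feature;
* demographics: race 0.70/0.15/0.15 European/African/Asian, age truncated
  normal around 63 years, sex 1:1, stage mildly age-correlated, BMI
  normal around 27.5;
* confounding: batch assignment by a logistic link to standardized age,
  sex, race and stage with a fixed coefficient pattern scaled by
  `confounding_strength` in [0, 1] — so the strength knob alone controls
  demographic-batch association, and a propensity model in those
  covariates is correctly specified;
* planted effects: selected non-degenerate species get a `2^log2_effect`
  multiplicative shift in group 1 of one factor; the truth object records
  them for recovery tests.

What the generator does **not** emulate: real per-cancer fungal profiles
or taxon names, contamination structure, correlations between species,
library-size dependence on batch, or missingness mechanisms other than
missing-at-random BMI. Passing recovery and error-control tests on these
cohorts therefore validates the machinery — transform correctness, weight
construction, the consensus rule's family-wise behavior — not the
biological fidelity of any particular dataset.

## Test problem sizes and behavior verified

The shipped tests run the full pipeline at cohort sizes chosen to keep the
suite fast while leaving the conclusions unambiguous: n = 300 samples, 40
species, 2 batches for the consensus properties (50 null seeds for
family-wise error control, 20 seeds with two planted 4-fold species for
recovery); n = 800 for the covariate-balance check; 666 samples for the
artifact reproduction; 100 samples x 40 features with 2,000 resamples for
the concordance statistics. Every quantitative expectation asserted in the
tests is computed there by an independent oracle (normal equations,
exhaustive confusion counts, full enumeration of group assignments,
hand-computed log-ratios) or by the construction itself.

## Known limitations

* The consensus rule is deliberately conservative; its power depends on
  the weakest member of the family (with structural dropout, the
  CLR/voom-style pipelines lose power fastest as the zero spike grows).
* Propensity clipping at [0.01, 0.99] bounds weights at the cost of mild
  misspecification in extreme strata.
* The MMUPHin-like correction handles location (fold-change) batch
  effects only, not batch-specific dispersion.
* Balance flags are diagnostics; the package never drops a contrast for
  imbalance on its own.
* Stage and histology enter propensity models only for samples with
  complete values; samples missing them are excluded from non-BMI
  contrasts rather than imputed.
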