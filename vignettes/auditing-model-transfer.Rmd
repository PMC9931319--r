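---
title: "Auditing cross-hospital transfer of ICU mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cross-hospital transfer of ICU mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icushift)
```

## The problem

A mortality risk model developed at one hospital is routinely applied at
another. `icushift` quantifies what happens when it is: how much
discrimination (AUC) and calibration (calibration slope) degrade on transfer,
whether the degradation differs between racial groups (false-negative-rate and
calibration-slope disparities), how different the source and target data
actually are (kernel two-sample tests), and which variables carry those
differences (constraint-based causal discovery over environments pooled with
context indicators).

Because the multi-center ICU databases this kind of audit runs on are
credentialed, the package ships a synthetic multi-hospital cohort generator
with a fully known structural causal model. Every downstream stage is
validated against that ground truth.

## The transfer protocol

Stays are grouped into environments — individual hospitals, US geographic
regions, or region x bed-band x teaching-status cells. For every ordered pair
of environments and each of `n_subsamples` replicates (100 by default, the
convention for this protocol):

1. draw a fixed number of stays (`n_per_environment`: 1631 for hospitals,
   5000 for regions) from the training environment without replacement —
   fixing n removes sample size as a confounder of the transfer comparison;
2. split 90/10 into training and validation parts;
3. freeze imputation and standardization statistics, fit an
   $\ell_2$-penalized logistic regression of in-hospital mortality on the 14
   model inputs (12 physiological worst values, age, elective surgery) on the
   training part;
4. evaluate the metric suite on the validation part and on a fresh draw of
   `n_per_environment` stays from the test environment.

The fitted model maximizes $\sum_i \left[y_i \eta_i - \log(1+e^{\eta_i})\right]
- \tfrac{\lambda}{2}\lVert\beta\rVert^2$ with the penalty on the coefficients
only; the default $\lambda = 1$ corresponds to the default inverse-strength
setting of common ML implementations. The solver is an IRLS/Newton iteration
with step halving; its zero-penalty limit is tested against `glm()` and the
penalized fit against `glmnet` (with $\lambda_{glmnet} = \lambda / n$).

Two protocol details are deliberate design choices. First, the test set is a
fresh fixed-size draw per replicate rather than the entire test environment:
fixed-n testing keeps the evaluation variance comparable across environments
of different sizes, consistent with fixing n for training. Second, diagonal
(train = test) cells evaluate on a disjoint draw that excludes the training
rows; when the environment is too small to supply one, the validation part is
reused and the replicate is noted in the run log. Independent draws are used
for each purpose (training draw, test draw, shift-test draws); nothing forces
them to share rows.

### Metrics

* **AUC** with midrank tie handling (equivalent to the Wilcoxon statistic).
* **Calibration slope (CS)**: slope of the logistic regression of observed
  outcomes on logits of the predicted risks. Risks are clipped to
  $[10^{-12}, 1-10^{-12}]$ before the logit, since penalized models can
  saturate numerically. Slope 1 is ideal; slopes below 1 indicate predictions
  that are too extreme.
* **Generalization gap**: test minus validation value of a metric; negative
  means degradation on transfer.
* **FNR at the test-prevalence threshold**: stays are classified positive at
  risk $\geq$ threshold (ties predicted positive), with the threshold set to
  the mortality rate of the test draw, treated as known at deployment.
* **DisparityFNR / DisparityCS**: minority-group minus majority-group value
  of FNR / CS; 0 is the equitable ideal. Race is used only for evaluation,
  never as a model input.
* **Percentage change**: $100 (test - train)/|train|$. The absolute-value
  denominator is a convention chosen here so the sign stays interpretable for
  negative training values.

Replicates where a metric is undefined (single-class sample, an absent group,
constant logits, a non-converged slope fit) are flagged `NA`, dropped from
aggregation, and counted in the run log. Aggregates are pooled medians and
quartiles over all pairs and replicates; disparity metrics are summarized
both signed and in absolute value, since either convention is defensible and
they answer slightly different questions.

## Dataset shift testing

Shift between two environments is measured by the squared maximum mean
discrepancy under a Gaussian kernel with the median-heuristic bandwidth
(median pairwise distance over the pooled sample, floored at $10^{-8}$).
The reported estimate is the unbiased U-statistic; for equal sample sizes the
paired form (matched cross terms excluded) is used, which cancels exactly to
zero on identical samples. Significance comes from a permutation test
(B = 200 by default) in which the identical statistic functional is evaluated
on the observed and on every permuted assignment, making the p-value exactly
valid under exchangeability; p-values live on the $(b+1)/(B+1)$ grid and are
thresholded at 0.05.

Features are imputed and standardized with pooled statistics before testing
so that scale differences do not dominate the distance; the outcome column is
excluded by default (a flag includes it). Pairwise results are averaged over
fixed-size subsample replicates and reported for the lower triangle only, as
the statistic is symmetric.

## Shift attribution with pooled-context causal discovery

To localize which variables shift directly with hospital, region, bed band,
teaching status, or race, the environments are pooled into one table with
numeric context indicator columns and the FCI algorithm is run on it. The
implementation is in-package: stable adjacency search with conditioning sets
of increasing size, possible-d-sep pruning, collider orientation, and
orientation rules R1-R4 plus the tail-completing R8-R10. Rules R5-R7 are
omitted — they fire only under selection bias, which the pooled-context
setting assumes away and the generator never produces. A d-separation oracle
can stand in for the data-based test, which is how the algorithm is validated
against ground-truth graphs.

Conditional independence uses the Fisher-z partial-correlation test with
$\alpha = 0.05$ and a maximum conditioning set size of 3 (both configurable).
Treating binary and ordinal indicator codes as linear-Gaussian variables is a
documented approximation, standard at this scale; it is also why the
generator keeps context effects linear in standardized context scores (see
below). Background knowledge encodes the pooled-context assumptions: context
indicators are exogenous (no incoming arrowheads) and mutually non-adjacent
except for declared hospital-to-attribute relations (region, beds, teaching,
race composition), and surviving context-system edges are oriented away from
the context. The "directly shifted" set of an indicator is its adjacency set
in the resulting PAG, any endpoint marks; one run on the pooled data produces
the summary (no stability selection is applied by default). Adjacency search
order is fixed and lexicographic, so results are exactly reproducible.

## The synthetic cohort generator

`default_scenario()` is the reference study condition: 10 hospitals of 1631
stays across 4 regions. Features are Gaussian on a latent standard scale and
affine-mapped to plausible clinical ranges; elective surgery is Bernoulli on
the logit scale. Context effects (hospital, region, bed band, teaching, race)
enter feature means linearly through standardized context scores, and a small
feature-to-feature mediation DAG (e.g. fever raises heart rate, hypotension
depresses urine output) creates indirect shift paths. Mortality is Bernoulli
with per-feature log-odds effects and race-modified coefficients for systolic
blood pressure and urea, so feature-outcome relationships differ by group.

Default shift pattern: the hospital indicator directly shifts age, race
composition, 3 of 6 vitals and 3 of 6 labs; race directly shifts 4 vitals, 4
labs, and elective surgery; region, bed band and teaching each shift a small
feature subset. Minority proportions decline across hospitals from 35% to 3%.
Per-hospital mortality intercepts were calibrated once by Monte Carlo so
empirical mortality rates run from about 4.2% to 9.0%, and then frozen.
Hospital effects follow a monotone gradient across hospital codes (an evenly
spaced standardized score), and region/beds assignments are scrambled
relative to that gradient: this keeps every context-feature dependence
within reach of a linear CI test while keeping the deterministic
hospital-to-attribute relations distinguishable from it. Missingness is
missing-completely-at-random, defaulting to 10% for labs and 5% for vitals
(nominal choices; real per-feature rates are not publicly characterized), and
never touches identifiers, race, or the outcome.

What the generator does *not* emulate: real marginal distributions
(worst values are unimodal Gaussian on the latent scale, with no bounds,
rounding, or heavy tails), informative missingness, within-stay time series
(a companion helper fabricates measurement series only to exercise
worst-value aggregation), temporal drift, and finer race categories than the
binary minority/majority grouping used in the analyses. Passing tests
therefore demonstrate that the pipeline's statistics behave correctly under
a known linear-Gaussian data-generating process — not that any specific
clinical dataset satisfies those assumptions.

## Preprocessing conventions

Ages above 89 are recoded to 90 (the HIPAA-obfuscation convention) and stays
under 16 are excluded; upstream eligibility criteria are represented by a
pre-computed boolean exclusion flag rather than re-derived. Worst values
follow the SAPS II severity sheet: minimum for Glasgow Coma Score, urine
output, and PaO2/FiO2 (whose severity points decrease monotonically in the
ratio), and the highest-scoring severity band otherwise, with point ties
broken by distance from the normal-range midpoint. Imputation defaults to
full-dataset means (the primary-analysis convention; its mild information
leakage from test rows into imputation values is the documented price, and
train-mean/train-median modes avoid it). Standardization uses training-set
means and *population* standard deviations — the common ML preprocessing
default. All 14 model inputs are standardized uniformly, including the
binary elective-surgery indicator; whether the original analyses standardized
that indicator is not determinable from public descriptions, so uniformity
was chosen.

## Problem sizes in the test suite

The packaged validation suite runs at desk scale: the transfer-null check
uses 10 environments of 1631 stays with 25 replicates per pair; permutation
validity uses 1000 null replicates at n = 100, d = 5, B = 200; calibration
and fairness identities use 100,000 and 2 x 50,000 rows; attribution accuracy
uses the default scenario at 20,000 stays; coefficient recovery uses a single
50,000-stay hospital with a vanishing penalty, compared within three
asymptotic standard errors from the observed Fisher information.

## Known limitations

* Fisher-z on binary/ordinal codes is an approximation; discrete or kernel
  CI tests are out of scope.
* The possible-d-sep phase caps conditioning sets at the same
  `max_cond_size` as the adjacency phase, for tractability.
* Deterministic hospital-to-attribute relations (region is a function of
  hospital) violate faithfulness in principle; the generator's scrambled
  assignments keep the induced partial correlations detectable, but analyses
  of other data should treat indicator adjacencies involving deterministic
  attributes with care.
* Aggregates provide replicate IQRs, not bootstrap confidence intervals, and
  no recalibration or fairness-mitigation method is included: the package
  audits transfer, it does not repair it.
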