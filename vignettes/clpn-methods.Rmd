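---
title: "Cross-lagged panel networks for two-wave symptom data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for two-wave symptom data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
```

## The scientific problem

Subclinical psychotic-like experiences (PLEs) — persecutory ideation,
bizarre experiences, perceptual abnormalities — co-occur and interact with
depressive symptoms, anxiety symptoms and adverse life events in young
adults. Cross-sectional symptom networks cannot say which symptom precedes
which. With two measurement waves, a *cross-lagged panel network* (CLPN)
orients edges in time: the edge $i \to j$ is the regression coefficient of
wave-1 variable $i$ predicting wave-2 variable $j$, controlling for all
other wave-1 variables and for socio-demographic covariates.

clpnet implements that workflow end to end for the canonical 24-node layout:

| construct | nodes | source |
|---|---|---|
| PLEs | PI, BEs, PAs | CAPE-P15 factor scores (5/7/3 items) |
| depression | PHQ1–PHQ9 | PHQ-9 items |
| anxiety | GAD1–GAD7 | GAD-7 items |
| adverse life events | A1–A5 | ASLEC factor scores (7/5/5/5/5 items) |

## Scoring and screening

The CAPE-P15 whole-scale *weighted score* is the sum of valid item scores
divided by the number of valid items; participants with a baseline weighted
score at or above the screening cut-off **1.57** form the *baseline
positive* group, the rest the *baseline negative* group. Published usage is
ambiguous about the boundary ("above 1.57" vs "the cut-off value 1.57 was
used"); clpnet treats the boundary as positive by default and exposes
`inclusive` in `classify_ples()`.

Factor scores are means of valid items. A factor score is missing when
fewer than 80% of its items are valid (the whole-scale weighted score is
exempt: its defining formula already handles missing items). Participants
with any missing node score are dropped listwise from the network stage;
the package performs no imputation. A `sum` scoring mode exists for
sensitivity analyses. The CAPE-P15 item-to-factor assignment and the ASLEC
27-item-to-5-factor map are configurable defaults (`default_instruments()`),
since the factor structures are instrument conventions rather than
properties of the data format. The ASLEC literature sometimes speaks of six
domains; the five-factor solution (punishment, loss, adjustment,
interpersonal stress, academic stress) is what enters the network, so five
is what the package scores.

Administrative exclusions run in a fixed order — duplicates (keep the
earliest record per participant and wave), speeders (response time under
5 minutes), psychotic-disorder history, refusals — and the flow report
asserts `input n − removals = output n` on every run.

## The estimator

Each of the 24 wave-2 node scores is regressed on all 24 wave-1 node scores
plus covariates with an L1 (LASSO) penalty, using glmnet. Design choices,
all exposed in `fit_config()`:

* **Lambda selection.** 10-fold cross-validation with seed-deterministic
  folds shared across the 24 regressions, selecting the
  prediction-error-minimizing lambda (`cv_min`, default). `cv_1se` and
  `fixed` modes exist; `fixed_lambda = 0` reproduces ordinary least squares
  and is verified against an explicit normal-equations oracle to 1e−6.
  `cv_min` keeps more weak edges (denser networks); `cv_1se` is markedly
  sparser and is the better choice when false edges are costlier than
  missed ones.
* **Standardization.** All node columns are z-scored per analysis group
  (population convention, denominator $n$) before fitting, so edge weights
  are comparable across nodes and centrality sums are meaningful. The two
  groups are standardized and fitted independently.
* **Covariates.** Dummy-coded with the first level as reference, included
  unpenalized by default (adjustment should not be shrunk away), and never
  entered into the weight matrix. Node scores are treated as continuous
  (Gaussian family); they are item/factor scores, not counts.

The diagonal of the resulting $24 \times 24$ matrix holds autoregressive
effects. These are retained in the matrix but removed from every centrality
and comparison computation.

`display_threshold()` filters edges below 0.05 in absolute weight *for
display and export only*; all computations run on the unthresholded matrix.

## Centrality

For the weight matrix $W$ with zeroed diagonal:
in-EI$(j) = \sum_{i \ne j} |W_{ij}|$, out-EI$(i) = \sum_{j \ne i} |W_{ij}|$,
and the bridge variants restrict the sums to edges whose other endpoint lies
in a different construct. Absolute-value sums are the default for the bridge
indices too, matching the verbal definition of expected influence; a signed
mode is provided because some toolkits sum raw weights. Two invariants are
enforced by tests: $\sum_j$ in-EI $= \sum_i$ out-EI $= \sum_{i \ne j}
|W_{ij}|$, and bridge $\le$ total elementwise.

## Accuracy and stability

*Edge accuracy*: nonparametric bootstrap (participants resampled with
replacement, network re-estimated per resample), percentile 2.5%/97.5%
intervals; 1,000 iterations for full runs. Percentile rather than
bias-corrected intervals: simplest to verify, standard in this literature.

*Centrality stability*: case-drop bootstrap. For each drop proportion the
network is re-estimated on a subsample and each centrality index is
correlated (Pearson, across the 24 nodes) with its full-sample value. The
CS coefficient is the largest drop proportion at which at least 95% of
subsamples correlate at least 0.7; both constants are arguments. CS of at
least 0.25 is conventionally acceptable, above 0.5 strong.

By default, resample refits reuse the full-sample per-node lambdas: the
penalty is treated as part of the frozen estimator, which keeps a 1,000-
iteration bootstrap tractable on one CPU and isolates sampling variability
of the coefficients from variability of the tuning step. `refit_lambda =
TRUE` re-runs CV inside every resample for the fully honest (and roughly
thirty-fold slower) variant. Resamples in which a node loses all variance
are redrawn and counted; input data with a zero-variance node is rejected
outright.

The case-drop grid defaults to 10%–75% by 5%. The subsample-size
precondition (at least ten participants per node) caps the usable grid for
small groups — at $n = 500$ the deepest admissible drop is 50% — so the
package's own stability checks use a 10%–50% (or 10%–40% at pipeline group
sizes) grid with 250 iterations per level.

## Comparing two networks

Three measures, computed on the estimated (post-LASSO) matrices without the
display threshold: (1) Pearson correlation of the vectorized off-diagonal
weight matrices (diagonal excluded by default, switchable); (2) the
proportion of the reference network's nonzero edges that are nonzero *with
the same sign* in the other network — sign-agnostic replication is offered
but a sign flip is not meaningful replication; (3) Pearson correlations of
each centrality index across the 24 nodes. Replication is deliberately
asymmetric (a property of the reference network's edge set); the matrix
correlation is symmetric.

## The synthetic cohort generator

No public accession exists for cohorts of this kind, so the generator is a
first-class, tested module that defines the package's study conditions:

* Wave-1 latent node scores are multivariate normal with a
  block-exchangeable covariance (within-construct correlation 0.40,
  between-construct 0.15).
* Wave-2 latents follow a linear VAR(1)-style system:
  $Z_2 = Z_1 B + X\Gamma + \varepsilon$, with a sparse ground-truth $B$
  (diagonal autoregression, configurable cross-lagged effects), additive
  covariate effects, and Gaussian disturbances (SD 0.8 by default).
* Item responses add item-level Gaussian noise (SD 0.6) to the node latent,
  then round and clip to the Likert range. This is the simplest mechanism
  consistent with the linear model the CLPN itself assumes — deliberately
  not an IRT measurement model.
* The latent mean of the PLEs factors is shifted by a bisection-calibrated
  amount so the realized screen-positive fraction matches the target
  (13.5% at wave 1; 7.18% at wave 2, the value implied by the published
  transition counts 104 + 137 of 3,358). Because the cut-off 1.57 is fixed,
  prevalence must be tuned through the distribution, not the threshold.
* Default autoregression places PLEs factors highest (PI 0.42, BEs 0.37,
  PAs 0.34 against 0.20–0.25 elsewhere); these values were calibrated once
  so the simulated screening dynamics reproduce realistic one-year
  persistence (≈23%) and incidence (≈4.7%) and then frozen.
* Administrative artifacts are injected at configurable rates converted to
  exact counts: duplicate wave-1 records with later timestamps, response
  times under 5 minutes, psychotic-history and refusal flags, and follow-up
  loss. Flagged sets are disjoint and follow-up loss only hits otherwise
  clean participants, so the cohort-flow ledger (3,866 collected → 3,728
  valid → 3,358 analyzed at the default rates) is exact by construction.
* Covariates: age uniform 17–22, sex Bernoulli(0.5), minority ethnicity
  8%, rural birth 30%, chronic condition 10%, mental-disorder history 6%,
  family history 5% — only their adjustment role matters.

**What the generator does not emulate:** ordinal response styles and
floor/ceiling asymmetries beyond rounding, group-specific dynamics (both
screening groups share one truth matrix $B$), informative missingness, and
measurement non-invariance across waves. Tests that pass on this generator
therefore certify the estimator and its statistics — recovery, stability,
comparison behavior — not distributional realism of any particular cohort.

A consequence worth knowing: Likert discretization plus item noise
attenuates single-item nodes (reliability ≈ 0.7), so absolute coefficient
recovery is biased toward zero in the discretized regime, while the
*pattern* (signs, support, relative magnitudes) is preserved. The package's
recovery checks are therefore phrased as correlation with the truth
(median r ≈ 0.93 at $n = 5{,}000$, 30 planted effects) and sign-correct
support recovery, and exact coefficient recovery is checked in the
noise-free continuous regime, where OLS reproduces the truth matrix to
within 0.02.

## Numerical choices and degenerate inputs

* Fixed-lambda glmnet fits run along a short descending lambda path ending
  at the target value (convergence threshold 1e−11), which stabilizes the
  unpenalized limit; lambda = 0 agrees with the normal-equations solution
  to better than 1e−6.
* Standardization uses population (denominator-$n$) moments; idempotent to
  1e−12.
* Zero-variance nodes abort estimation with the node named; zero-variance
  covariate dummies are silently dropped (they arise routinely in small
  resamples).
* Ties at the screening cut-off go to "positive" (inclusive boundary).
* An empty reference edge set makes the replication proportion `NA` with an
  explicit flag, never a division by zero; undefined transition denominators
  behave the same way.
* One global seed fans out to stage seeds via the documented arithmetic in
  `derive_seed()`, so every stage can be reproduced in isolation; all
  derived seeds stay below $2^{31}$.

## Problem sizes used by the package's own checks

The test suite runs the full estimator at $n$ up to 8,000 (stability),
5,000 (recovery, 20 planted-truth replicates; comparison, 10 independent
sample pairs), and uses 200–250 bootstrap iterations; the acceptance script
runs the complete two-group pipeline at the default cohort size (3,755
unique respondents) with 1,000 bootstrap iterations and 250 case-drop
iterations per level. These sizes were chosen to match the cohort scale the
package targets while keeping a full verification run on a single CPU
comfortable.

## Known limitations

Single-lag, two-wave design only: no contemporaneous (Gaussian graphical)
network, no mixed graphical models for ordinal nodes, no measurement
models. Group networks are estimated fully independently, which is the
transparent choice but forfeits shrinkage that a joint model could offer.
The replication proportion depends on the estimator's sparsity (a denser
`cv_min` network replicates differently than a `cv_1se` one); comparisons
should state the selection rule used.
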