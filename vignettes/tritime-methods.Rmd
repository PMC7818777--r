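---
title: "Methods: tensor-based longitudinal multi-omics case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor-based longitudinal multi-omics case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritime)
```

# The model and its assumptions

`tritime` analyses matched case-control cohorts whose omics
measurements are re-aligned on a countdown to a clinical anchor event
(months before seroconversion, MBSC). Each omics block is arranged as a
three-way array `X` of subjects x features x timepoints, with
`x[i, j, k]` the value of feature *j* in subject *i* at visit bin *k*.
Working on the tensor rather than a flattened matrix keeps the time
mode explicit: the model returns one set of loadings per mode, so the
contribution of subjects, features, and disease progression can be
read separately.

The assumptions built into the pipeline are:

* **Exchangeable matched sets.** A case and its matched control(s)
  differ only through disease progression; everything shared (age, sex,
  country, batch) cancels in the within-set normalization.
* **Low-rank structure.** Both the imputation model (Tucker3) and the
  classifier (trilinear PLS) assume the signal concentrates in a few
  multilinear components; noise is left in the residual.
* **Block-level visit missingness.** A missed visit removes a whole
  block vector at a subject x timepoint, not scattered single cells.
  The completeness rule (at least 3 of the 5 timepoints) bounds how
  much any subject is imputed.

# Stages and the choices inside them

## Binning

Visits are mapped to the bins 12, 9, 6, 3, 0 MBSC with boundaries
10.5–13.5, 7.5–10.5, 4.5–7.5, 1.5–4.5, and 1–1.5 months. The
boundaries are closed on the left and open on the right, except the
last (13.5 is kept), so every printed boundary value has a unique bin;
values below 1 MBSC fall outside the design and are dropped with a
logged count. Multiple values from one subject inside a bin are
averaged. Timepoints are ordered by decreasing MBSC everywhere, so
mode 3 reads chronologically toward the event.

## Completeness filter

Subjects observed at fewer than 3 of 5 timepoints cannot be imputed
credibly, so they are excluded from model building — and because the
within-normalization needs complete sets, the *whole matched set*
moves to the validation pool whenever any member fails the rule. Those
subjects are still used: the selected signature is validated on them
per timepoint with LDA (see below).

## Tucker3 imputation

Missing cells are filled with the observed mean, a Tucker3 model is
fitted by alternating least squares (higher-order orthogonal
iteration, HOSVD start — deterministic, no seed), the filled cells are
replaced by the reconstruction, and the cycle repeats. Convergence is
declared when the relative change in the sum of squared differences of
the imputed cells between successive iterations drops below `tol`
(default `1e-7`); an alternative criterion tracking the reconstruction
error on observed cells is selectable. Observed cells are never
altered, and the mask keeps marking imputed cells so downstream stages
can distinguish provenance. Imputation runs per block; blocks are
never concatenated before imputation.

Mode ranks default to the DIFFIT heuristic: all feasible rank triples
with total rank up to a cap are fitted, the best fit per total rank
forms a monotone envelope, and the chosen total maximizes the ratio of
successive fit gains. Two guards make the rule deterministic: gains
below 1% of the total sum of squares never win (pure-noise tensors
then fall back to (1,1,1)), and ties break toward the smaller total.

Normalization order: imputation runs first, on raw binned values, and
within-normalization second. The reverse order is possible in
principle, but normalizing before imputing would feed the imputation
model cells whose set means were computed from partially missing sets;
imputing first keeps both steps defined on complete inputs.

## Case-control within-normalization

Per set, feature, and timepoint the set mean is subtracted from every
member. With several controls the control mean is computed first and
then averaged with the case value, so the case and the control pool
weigh equally regardless of the number of controls. Consequences used
downstream: for 1:1 sets the normalized case and control values sum to
zero exactly; for 1:many sets the case plus the mean of the controls
is zero. When only one side of a set is observed at a cell the cell is
set missing rather than trivially zeroed (a zero would claim perfect
case-control agreement that was never measured).

## NPLS-DA

The classifier is trilinear PLS (tri-PLS2) with a dummy-coded class
response. Per component, the feature-mode and time-mode weights are
the dominant singular pair of the J x K matrix `Z = X_(1)' u`, which
maximizes the squared covariance between the tensor projection and the
response score; the subject score is the tensor contracted with the
rank-1 weight `w_J ⊗ w_K`. Only the response is deflated. This keeps
an exact invariant — every component's scores are the plain
contraction of the centered tensor with that component's weights — and
makes the single-timepoint case coincide with a standard two-way PLS
with response-only deflation (the equivalence is exercised in the test
suite against an independently written matrix implementation and
against `mixOmics` for the first component).

The discriminant layer is LDA on the subject scores (default); the
inner regression with a midpoint cutoff is available as an
alternative. Ties in posterior probability go to the first class in
sorted label order. Weight signs are fixed so the largest-magnitude
feature weight per component is positive.

**Cross-validation with matched sets.** Q² = 1 − PRESS/TSS on the
dummy response. A subtlety matters here: after within-normalization a
case's profile is the mirror image of its matched controls'. If a set
is split across CV folds, the held-out subject's profile is present in
training with the opposite sign and label, and Q² inflates massively —
on pure-noise cohorts, subject-level leave-one-out reports Q² around
0.5 where the truth is ≤ 0. `crossValidate()` therefore holds out
whole case-control sets whenever the pairing is known (an
`OmicsTensor` input, or an explicit `groups` argument): "LOO" then
means leave-one-set-out, and k-fold assigns sets, not subjects, to
folds. On un-normalized plain arrays, subject-level class-stratified
folds are used. The null-calibration tests (mean Q² ≤ 0.1 at zero
effect, permutation type-I error at nominal level) pass under
set-level folds and are unattainable without them.

**Multiblock integration.** The integrated model concatenates blocks
feature-wise over their shared subjects after scaling each block to
unit total sum of squares, so a large block cannot dominate the
covariance; with different matching ratios per block, the shared
subjects are the intersection (each case plus the control(s) common to
every block).

## VIP selection

The importance measure is Wold's VIP,
`VIP_j = sqrt(p · Σ_h SSY_h w_jh² / Σ_h SSY_h)` with unit-norm
weights, where `SSY_h` is the response sum of squares explained by
component *h*. Three arrangements are computed:

* `vip2d`: standard two-way VIP on the subjects x (features ×
  timepoints) unfolding — one value per feature per timepoint. The
  unfolding is the full wide matrix; per-feature scores collapse over
  timepoints by max (default) or mean.
* `vip3d_model1`: from the three-way model, the per-(feature,
  timepoint) weight is the Kronecker element `w_jh · w_kh`; the VIP is
  averaged over timepoints per feature and component (time mode
  constrained).
* `vip3d_model2`: per-(feature, timepoint, component) VIP summed over
  timepoints within each component.

Both three-way variants collapse over components by a mean weighted
with each component's explained response share. Thresholding keeps
features *strictly above* the block's VIP percentile (linear
interpolation; 99 for gene expression, 95 for metabolomics-like
blocks — with a few hundred features the gene cut keeps only a
handful, so the synthetic-scale configurations in this package often
use 95 throughout). The three selections plus all pairwise and
three-way unions and intersections are refitted and cross-validated;
the winner has the best Q², ties broken by R² and then set size.

## Validation

* **Random-feature permutation:** the observed set's R²/Q² against
  `n` size-matched uniform draws from the block's universe;
  `p = (1 + #{null ≥ obs}) / (n + 1)`, one-sided.
* **Label permutation:** case/control roles are flipped per whole set
  with probability 1/2 (the exchangeable unit under matching);
  unpaired shuffling is available.
* **Per-timepoint LDA:** for each timepoint, an LDA on the analysis
  subjects' selected-feature slice predicts the validation subjects
  observed there. When features outnumber the (tiny) sample, the
  pooled covariance is shrunk toward its diagonal with an analytic
  intensity before inversion. Timepoints with fewer than 2 subjects or
  one class report NA.

## Time-window partial-correlation networks

Only normalized case values enter (they encode the case-control
divergence). Differences of consecutive timepoints give four windows
(12to9, 9to6, 6to3, 3to0); the sign convention is later minus earlier,
i.e. change in the direction of progression. Per window, elastic-net
stability selection picks the active features: the mixing parameter α
is scanned from 0 (ridge) to 1 (lasso) in steps of 0.1, each α scored
by out-of-bag deviance over bootstrap refits (the response is the
case/control outcome by default, the window's first principal
component in unsupervised mode; the penalty for the final stage comes
from cross-validation at the winning α since nothing in the procedure
pins it otherwise), and features with a nonzero coefficient in at
least one of the final bootstrap fits are kept.

Partial correlations are full-order:
`pcor(i, j) = −P_ij / sqrt(P_ii · P_jj)` with `P` the inverse
covariance. When `n ≤ p + 10` the covariance is first shrunk toward
its diagonal (Schäfer-Strimmer analytic intensity, implemented in the
package); otherwise the sample covariance is inverted directly.
Networks keep edges with |pcor| > 0.7; nodes carry the molecule kind
(gene / metabolite / vitamin), the mean normalized case value at the
window's first timepoint, and an up/down flag. Windows are compared by
the excess kurtosis of their off-diagonal partial-correlation values
(negative = platykurtic, positive = leptokurtic) and two-sample KS
tests between consecutive windows.

## Enrichment

Gene sets are scored per timepoint by permutation on the VIP ranking:
the observed statistic is the sum (and the mean) of the members'
values, the null redraws member labels from the universe, and the
smaller of the two modality p-values is retained. Gene-label (not
sample-label) permutation is the only option that is defined here,
since only rankings enter the operation. Per set, the p-values of all
non-empty timepoint subsets are combined with Fisher's method
(`−2 Σ log p ~ χ²` on `2k` df), BH-corrected across sets within each
combination, and a set is flagged when any adjusted p ≤ 0.05. Signed
pathway scores are `(1 − p) · sign(mean value of significant
members)`. Metabolite classes are scored per timepoint by paired
t-tests (Welch when pairing is incomplete), a one-sided 2x2 Fisher
exact test of class membership against significance, BH correction
across classes, and an FDR cut at 0.2.

# The synthetic cohort: what it emulates and what it does not

`generateCohort()` draws feature values as i.i.d. Gaussian noise plus
a subject-level random intercept (SD = half the noise SD) — the
minimal structure that makes within-set normalization non-trivial —
and adds the planted effect to cases only:
`effectSize × profile[k] × noiseSd` at the informative features, with
the default time profile (1.0, 1.0, 0.6, 0.4, 0.4) loading the signal
on 12 and 9 MBSC, mirroring the early-divergence pattern this class of
study reports. Matching is 1 control per case for the gene-expression
block and 3 for metabolomics/dietary blocks. Observation times are
jittered uniformly inside the bin boundaries. Missingness is MCAR at
the subject x timepoint x block level, capped so regular subjects keep
at least 3 timepoints; a configurable group of incomplete sets (1–2
observed timepoints) feeds the validation route.

What the generator does *not* emulate: pathway-level co-regulation,
batch or platform effects, heavy-tailed or skewed abundance
distributions, informative (non-random) missingness, and any real
biology in the feature identities. Passing tests therefore demonstrate
that the machinery recovers planted multilinear structure under the
stated noise model — not that it would rank true biology correctly in
data with correlated features or structured artefacts.

# Numerical choices

* Tucker3 ALS: HOSVD initialization, relative fit-change tolerance
  1e-8, monotonicity asserted every sweep; rank triples must satisfy
  each rank ≤ product of the other two.
* Imputation: default tolerance 1e-7 on the movement of imputed cells.
* NPLS inner loop: score-change tolerance 1e-12; a tiny ridge
  (1e-12 × scale) stabilizes the inner regressions.
* Percentile thresholds use `quantile(type = 7)` (linear
  interpolation) and strict inequality; ties at the threshold are
  excluded.
* LDA on scores adds a 1e-8-scaled ridge to the pooled covariance;
  the high-dimensional validation LDA uses analytic diagonal
  shrinkage.
* Permutation p-values use the conservative `(1 + k) / (n + 1)`
  estimator; p = 0 inputs to Fisher's method are clipped to 1e-16
  with a warning.
* All stage seeds derive deterministically from one global seed
  through a small multiplicative stream, so any stage can be re-run
  in isolation with its logged seed.

# Problem sizes used by the tests

The suite exercises the pipeline at desk scale: cohorts of 10–40
matched sets with 30–400 features per block, DIFFIT grids to total
rank 10 on tensors around 20 x 15 x 5, 100-draw permutation tests
(200 repetitions for the type-I calibration), 500-set enrichment
nulls, and two full 40-pair three-block pipeline runs for the
reproducibility check. These sizes keep the complete suite within a
coffee break while leaving every statistical property testable.

# Known limitations

* Two classes only; the discriminant layer would need a multiclass
  coding for more.
* The integrated model restricts to subjects shared by all blocks;
  with different matching ratios this drops the extra controls of the
  1:3 blocks.
* Elastic-net stability selection with "appears at least once" is
  permissive by construction; with many bootstrap fits it approaches
  the union of all features that ever enter the path. Tighter
  appearance thresholds are a one-line change but are not what the
  procedure specifies.
* DIFFIT compares fits along the total-rank envelope; for tensors
  whose gains decay smoothly (pure noise at small size) the ratio
  criterion has no distinguished elbow, which is why the flat-gain
  fallback exists.
* The per-timepoint validation LDA sees very small samples (single
  digits per timepoint in realistic settings); its accuracies are
  reported with their `n` and should be read accordingly.
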