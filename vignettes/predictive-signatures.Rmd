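---
title: "Constructing and evaluating predictive survival signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating predictive survival signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predsig)
```

## The model and its assumptions

`predsig` targets two-arm clinical trials with a right-censored time-to-event
endpoint (progression-free survival, in months) and a gene expression profile
per patient. The statistical object is a proportional-hazards model with a
treatment-by-covariate interaction,

$$\log\frac{\lambda(t \mid z, x)}{\lambda_0(t)}
  = \beta_0 z + \sum_{l=1}^K \beta_l \tilde x_l + z \sum_{l=1}^K \gamma_l \tilde x_l,$$

where $z$ is the randomized arm (0 control, 1 experimental) and
$\tilde x_1..\tilde x_K$ are a handful of covariates derived from the
expression matrix. The assumptions are the usual Cox ones — proportional
hazards within covariate strata, censoring non-informative given $(z, x)$ —
plus randomization of $z$, which is what licenses reading $\gamma$ causally
as differential treatment effect. The baseline hazard $\lambda_0$ is never
estimated: the biomarker

$$\Delta\xi(x) = \xi(1, x) - \xi(0, x) = \beta_0 + \gamma^\top \tilde x$$

depends only on the coefficients. $\Delta\xi$ is the log of the
experimental-to-control hazard ratio *for that patient*; negative values
favor the experimental arm. Direct effects $\beta_l$ cancel exactly — a
signature can be strongly prognostic and carry no predictive information at
all. Three regimes follow from $\gamma$ (exposed by `classify_scenario()`):
no interaction ($\gamma \approx 0$: $\Delta\xi \equiv \beta_0$, the signature
is only prognostic), moderate interaction (one arm favored everywhere but to
measurably different degrees), and strong interaction ($\Delta\xi$ changes
sign over the covariate range: the optimal arm flips between patients).

Fitting is by partial-likelihood maximization with Efron handling of tied
event times, delegated to the survival ecosystem's workhorse; the package
adds the design construction `[z, x̃, z·x̃]`, collapse of zero-variance
covariates (their coefficients are reported as exact zeros), a rank check
against collinear designs, and a runaway-coefficient guard (|coef| ≥ 50 is
treated as separation and flagged as non-convergence, so resampling loops can
count and skip such replicates). Tests verify the fit against an independent,
hand-written Efron partial likelihood maximized by iterated grid search.

## Dimensional reduction

With $p \sim 10^4$ genes and $n \sim 200$ patients the interaction model must
be regularized by reducing $x$ to $K \ll p$ covariates before the Cox fit.
Three strategies are provided, all fitted strictly on training samples and
applied to held-out samples with frozen state:

* **subC** (subtype correlation): each profile is correlated with reference
  centroids of molecular subtypes over their shared genes and
  Fisher-transformed, $\zeta_j = \tanh^{-1} r(c_j, x)$; the covariates are
  the mean-centered $\zeta'$. Correlations are clipped to $\pm(1 - 10^{-6})$
  because the transform diverges at $|r| = 1$. Discrete subtype calls are
  deliberately avoided — the continuous correlations retain more
  information. Centering means are training-set state and are recomputed per
  bootstrap replicate.
* **MOA** (mechanism of action): the gene pool is first restricted to an
  a-priori list representing the drug's presumed mechanism; genes are then
  ranked by the Wald p-value of the interaction coefficient in single-gene
  Cox models, the top `mtop` are kept, and (by default) their first principal
  component is the single covariate. The alternative reading — the selected
  genes used directly as `mtop` covariates — is exposed as
  `moa_covariates = "genes"`; the PC1 default parallels the SPC construction
  and keeps K fixed while `mtop` is tuned.
* **SPC** (supervised principal components): the same interaction-p selection
  applied genome-wide, followed by the top-K right singular directions of the
  gene-centered selected submatrix. K = 1 is the default throughout. PC signs
  are fixed by making each component's largest-magnitude loading positive, so
  score signs are reproducible across runs.

Wald p-values are used for the per-gene ranking because the alternative
(likelihood-ratio or score tests per gene) triples the cost at a
20,000-gene scale for no ordering change of practical consequence; fits that
fail or run away are assigned p = 1 and flagged rather than dropped, so the
ranking length is stable. Ties break by |interaction coefficient| descending
and then gene id, making selections deterministic.

## Pre-validation, the hROC, and the area between curves

All evaluation uses pre-validated scores: the samples are split into k = 5
arm-stratified folds of near-equal size (fold labels are dealt round-robin
over the shuffled arm-0 samples followed by the shuffled arm-1 samples, so
overall and per-arm fold sizes each differ by at most one), each fold is
scored by a model trained on the other folds, and the n pooled scores are
treated as if produced on an independent test set.

A threshold $\Delta\xi_c$ splits patients into sensitive
($\Delta\xi \le \Delta\xi_c$) and relatively-resistant groups; within each
group the arms are compared by a univariate Cox model. The reported p-value
is the Cox score test, which for a binary grouping is the log-rank test (the
equality was verified numerically against `survdiff` before freezing the
choice). Sweeping the threshold through the score order gives one point per
distinct partition — n + 1 for tie-free scores — and expresses hR(S) and
hR(R) parametrically in the sensitive fraction q: the hazard-ratio ROC. At
q = 1 the sensitive group is everyone, so hR(S) equals hR(all) exactly; the
degenerate complements at the endpoints are marked undefined. A group
contributes a defined point only when each arm has at least 5 subjects and 1
event (`min_n`, `min_events`), since hazard ratios from vanishingly small
groups are dominated by variance; undefined points are excluded from
integration support.

The curves are summarized by the area between them after the symmetrizing
transform $\sigma(h) = (h - 1)/(h + 1) = \tanh(\tfrac12\log h)$, which maps
$(0, \infty)$ to $(-1, 1)$ with $\sigma(1) = 0$ and
$\sigma(1/h) = -\sigma(h)$:

$$A_{bc} = A_{hR} - A_{hS}, \qquad
  A_{h\cdot} = \int \sigma(h_\cdot(q))\, dq \text{ (trapezoidal, observed
  q-points, no renormalization by support width)}.$$

The orientation is chosen so that **better benefit concentrated in S (lower
hR(S), higher hR(R)) gives positive Abc**; with the increasing $\sigma$ this
is exactly the order $A_{hR} - A_{hS}$. Two closed forms anchor the
convention in tests: identical curves give $A_{bc} = 0$, and constant curves
$hR(R) = 3$, $hR(S) = 1/3$ over $q \in [0,1]$ give $A_{bc} = +1$. Each area
is bounded by 1 in magnitude; empirically $|A_{bc}| \le 1.5$ because the two
curves are tied to a common hR(all).

## Resampling: predictive risk and the permutation control

Bootstrap resampling wraps the *entire* cross-validated pipeline: each of B
replicates resamples the n patients with replacement, regenerates the k folds
from scratch, reruns pre-validation, splits at the fixed threshold, and
records hR(S)\*, hR(R)\*, n(S)\*, Abc\* and ρ\* = hR(S)\*/hR(R)\*. Summaries
are medians and 2.5/97.5 percentile intervals (the simplest interval
consistent with reporting bootstrap distributions); the predictive risk is
pRisk = Pr(Abc\* < 0), the estimated probability that the signature fails
under generalization. ρ is computed within each replicate — the median of
ratios, never the ratio of medians.

One resampling design choice matters and was made on the evidence of the
package's own negative control. If the duplicates created by resampling may
land in different folds, a patient's outcome enters the training of the model
that scores its clone; on permuted-label data this leaks optimism (median
permuted pRisk near 0.27 and median ρ\* near 0.7 instead of 0.5 and 1 at
n = 100–200). The default is therefore `duplicate_folds = "grouped"`: all
copies of a source patient share a fold (folds are still regenerated from
scratch each replicate). With grouping, the permuted control is calibrated
(median pRisk ≈ 0.55, median ρ\* ≈ 0.95 in the test suite's simulations).
The literal instance-level variant remains available as
`duplicate_folds = "free"`.

The negative control itself (`permutation_control()`) permutes the
expression-to-clinical linkage **once** (a single fixed permutation from the
seed), which preserves both marginals while destroying any
expression–outcome correlation, then bootstraps the permuted data. The
resulting null Abc\* distribution yields the one-sided
$P = \Pr(A_{bc}^{null} > A_{bc}^{obs})$ for the observed, non-permuted,
non-bootstrapped Abc. Note that a single permutation is itself a random draw:
its spurious Abc may sit off zero, so individual permuted pRisk values spread
widely around 1/2 and only their distribution over master seeds is
calibrated.

## Threshold selection and decision summaries

Ad hoc thresholds (e.g. the median score, or a clinically motivated
hazard-ratio bound $e^{\Delta\xi_c}$) are supported directly. The principled
alternative minimizes

$$\varphi(q) = -q\,(h_0 - h_S(q)) + (1 - q)\max(1 - h_R(q),\, 0)$$

over the hROC's defined grid points — no smoothing or interpolation, because
the curves are step functions of the data; ties break to the smallest q. The
first term rewards benefit concentrated in the sensitive fraction, the second
charges for denying beneficial treatment to the resistant fraction and is
gated out when $h_R(q) > 1$. An optional box constraint (`qmin`, e.g. 0.25)
encodes the trial-accrual requirement that the selected fraction not be too
small. `optimize_mtop()` sweeps the feature count against Abc with a fixed
fold assignment, reusing the per-fold gene rankings (which do not depend on
mtop); ties prefer the smallest model.

The patient selection matrix reports Kaplan–Meier median PFS per
{arm × group} cell with the margins that answer the two distinct questions:
columns compare arms within a response group (predictive), rows compare S
versus R within an arm (prognostic). KM medians use the convention
median = inf{t : Ŝ(t) ≤ 0.5}; unreached medians propagate as NA, including
into the per-group ΔPFS (experimental-minus-control median).

## The synthetic generator: what it emulates and what it does not

`generate_trial()` draws K latent standard-normal factors per patient,
embeds them in gene blocks (configurable size and loading per factor, plus
independent Gaussian noise on the log2 scale), optionally structures
expression as mixtures of supplied subtype centroids whose mixing weights
carry the latent signal, and draws event times from the interaction
proportional-hazards model with a Weibull baseline (shape 1 = exponential by
default — Cox inference is baseline-agnostic, and the shape is exposed for
robustness checks). Censoring is the minimum of an independent exponential
and an administrative cutoff, matching the model assumptions under test. The
true $\Delta\xi = \beta_0 + \gamma^\top w$ is returned for oracle
comparisons.

Defaults mirror the study conditions the method targets: n = 209 patients
randomized 1:2 control:experimental, a moderate interaction
($\beta_0 = -0.7$, $\beta = -0.5$, $\gamma = 1$ on one latent factor, so the
experimental arm is favored for most but not all patients), an exponential
baseline of 0.12 events/month (median PFS ≈ 6 months at covariate zero,
typical of late-line metastatic disease), light independent censoring
(0.03/month) and administrative censoring at 30 months, giving roughly
20–30% censoring overall.

What the generator does **not** emulate: count-level RNA-seq noise (inputs
are modeled post-log2, post-normalization, because that is what the method
consumes), batch effects, correlated censoring, or non-proportional hazards.
Passing tests therefore demonstrate correctness of the machinery and
calibration under the stated model, not robustness to those violations.

For the feature-count sweep a two-factor design is used: a small interacting
block plus a larger purely *prognostic* factor. This is deliberate — with
only independent noise genes, PC1 of the standardized selected set is barely
diluted by overselection and the Abc-vs-mtop profile is nearly flat; a
competing prognostic factor is the realistic mechanism that makes
overselection costly, and it produces the expected peak near the true block
size.

## Numerical choices and degenerate inputs

* Standardization uses the sample (n−1) standard deviation; zero-variance
  genes are dropped with a warning and recorded, and stored training
  means/sds are reapplied verbatim to held-out data.
* Quantile normalization assigns the cross-column mean of order statistics,
  averaging across tied ranks.
* Identifier matching is exact-string and case-sensitive; missing expression
  values are rejected rather than imputed (the pipeline has no imputation
  step).
* PFS is accepted in months; a days flag converts with month = 365.25/12.
* Cox convergence: relative log-partial-likelihood change < 1e−9 within 100
  iterations; non-converged or separated fits are flagged, never silently
  used.
* All randomness flows from explicit integer seeds; resampling derives
  per-replicate streams from one master seed, and user RNG state is restored
  after every seeded operation.

Test-suite simulation sizes (n = 100–600, B = 8–30 bootstrap replicates,
200 replicates for Wald coverage, 4–10 replicates for ranking/sweep
properties) were chosen as the smallest designs at which the checked
properties are stable; the acceptance script uses n = 209/210 and B = 200.

## Known limitations

* hROC hazard ratios at extreme q are excluded below 5 subjects or 1 event
  per arm; the Abc support therefore shrinks slightly with heavy censoring,
  and Abc values are comparable only at equal support conventions (support is
  recorded in the result).
* The bootstrap treats the decision threshold as fixed; optimizing
  $\varphi(q)$ inside each replicate would widen the intervals.
* `mtop` is tuned once, outside the bootstrap, so the reported intervals do
  not account for selection of `mtop`.
* Global standardization before cross-validation (the default, matching
  common practice) reuses all-sample gene moments; the strictly leakage-free
  per-fold variant is available (`standardize_mode = "fold"`) and is what the
  leakage tests exercise.
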