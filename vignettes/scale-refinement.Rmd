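---
title: "Refining an ordinal scale's coverage of a latent severity continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining an ordinal scale's coverage of a latent severity continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redext)
```

## The measurement model

redext treats each ordinal item $i$ with $k_i$ response options as a
coarsened view of a continuous underlying variate
$y_i^\ast = \lambda_i \theta_{d(i)} + \varepsilon_i$, where
$\theta = (\theta_1, \theta_2, \theta_3)$ are latent domain scores (loss of
control over eating, lack of satiety, preoccupation with food) with a
standard-normal marginal distribution and correlation matrix $\Psi$,
$\lambda_i \in (-1, 1)$ is the item's loading, and
$\varepsilon_i \sim N(0, 1 - \lambda_i^2)$.  This is the *delta
parameterization*: every $y_i^\ast$ has unit total variance, so item
thresholds $\tau_{i1} < \dots < \tau_{i,k_i-1}$ live on one common probit
scale and are directly comparable across items.  The observed response is
the number of thresholds below $y_i^\ast$, and at a trait value where
$\lambda_i \theta = \tau_{ic}$ the probability of responding in category
$c$ or higher is exactly 50% — which is what makes a threshold an
interpretable *severity*: the point on the continuum an item "switches on".

Assumptions worth keeping in mind: normal latent traits and residuals
(hence polychoric, not polyserial or Pearson, correlations), one domain per
item, and monotone item response functions.  The model is estimated in
three steps, never by full-information maximum likelihood:

1. *Thresholds* from univariate margins:
   $\hat\tau_{ic} = \Phi^{-1}(\hat p_{i1} + \dots + \hat p_{ic})$.
2. *Polychoric correlations* by two-step ML: thresholds held fixed at their
   marginal estimates, the latent correlation $\rho$ maximizing the
   multinomial likelihood of the pairwise contingency table under a
   bivariate normal, solved by a bounded scalar optimizer (tolerance
   $10^{-6}$).  Two-step rather than joint ML keeps the threshold
   definition purely marginal, which is what the severity analysis uses.
3. *Factor structure* by least squares on the polychoric matrix:
   $F = \sum_{i<j} w_{ij} (\hat\rho_{ij} - \lambda_i \lambda_j
   \psi_{d(i)d(j)})^2$ with $w_{ij} = 1$ (ULS, the default) or
   $w_{ij}$ the inverse asymptotic variance of $\hat\rho_{ij}$ computed
   from the Fisher information of the pair likelihood (DWLS).

The test statistic is the *unscaled* $\chi^2 = (n_{\mathrm{eff}} - 1)
F_{\min}$.  No mean-and-variance (robust) adjustment is applied: that
correction needs the full asymptotic covariance matrix of the polychoric
estimates, and nothing downstream — thresholds, loadings, gaps, selection —
depends on the scaled statistic.  The consequence is that CFI and RMSEA
printed here are **not numerically comparable** to robust weighted
least-squares output from general SEM software, even on identical data;
SRMR, a pure residual summary, is comparable.  Fit indices are reported and
never used as a gate: the refinement decisions rest on thresholds and
loadings.

`n_eff` is the rounded mean of the pairwise complete-observation counts
(equal to $n$ without missingness); with pairwise deletion no single $n$
exists, and the mean is a neutral choice for a statistic we deliberately do
not lean on.

## Tunable constants

| Constant | Default | Units | Why |
|---|---|---|---|
| gap criterion | 0.5 | logits | a half-logit spacing between thresholds is conventionally treated as a clinically meaningful discontinuity in coverage |
| logistic-to-normal constant | 1.7 | — | logistic and normal-ogive response curves nearly coincide after rescaling by 1.7; thresholds here are on the normal metric |
| gap width in normal units | 0.5 / 1.7 ≈ 0.294 | normal units | carried at full precision everywhere; 0.29 is a display rounding |
| half-window | 0.294 / 2 | normal units | a gap is any region farther than this from *every* reference threshold |
| retention cutoff | 0.45 | loading | screening keeps candidates explaining substantial common variance; the comparison is ≥ (boundary included) |
| trait range | person range ± 0.25 | normal units | maps are bounded by where respondents actually sit, with a small margin |
| EAP quadrature | 49 Gauss–Hermite nodes | — | inexpensive and accurate far beyond scoring needs for ≤ 20 items |

## The gap engine

Given sorted reference thresholds $t_1 < \dots < t_m$ and half-window $h$:
each consecutive pair with $t_{q+1} - t_q > 2h$ contributes the interior
interval $(t_q + h,\; t_{q+1} - h)$, and the regions below $t_1 - h$ and
above $t_m + h$ (clipped to the trait range) are edge gaps.  By
construction no interval point is within $h$ of a reference threshold, and
the construction commutes with translation of all inputs — both properties
are asserted to $10^{-12}$ in the test suite.  Coverage containment is
*closed*: a candidate threshold exactly on an interval endpoint counts as
covering, avoiding knife-edge floating-point nondeterminism.

Severities are mapped as raw underlying-variate thresholds $\hat\tau$
(matching how thresholds are extracted from fitted categorical models);
`threshold_map(..., irt_scale = TRUE)` divides by the loading for
2-parameter-style locations instead.

## Selection policy

The published refinement ended with authors hand-picking a domain-balanced
set.  That judgment is encoded as a deterministic rule: greedily take the
candidate covering the most uncovered gaps; break ties by (1) the domain
least represented among reference-plus-selected items, (2) lower mean
severity, (3) lexicographic id; stop when every coverable gap is covered.
`force_include` / `force_exclude` let a published composition be pinned
exactly.  Greedy set cover is not guaranteed minimal in general; on the
bounded fixtures in the test suite (≤ 10 candidates, ≤ 6 gaps) it is
verified against exhaustive enumeration, and on the encoded published
scenario it reproduces the four-item extension (9 + 4 = 13 items) without
any forcing.

Rater agreement on domain categorization is Fleiss' kappa for ≥ 3 raters
and Cohen's kappa for 2; mean pairwise Cohen is available because
multi-rater kappas reported in the literature are sometimes that variant,
and the two do not coincide.

## The synthetic-data generator

`make_preset()` emulates the structure of the validation studies, not any
participant's data:

* **STUDY1_LIKE** — n = 238, mixed 2/3/4/5-option formats (the original
  instruments' own scales), factor correlations 0.72–0.92.
* **STUDY2_LIKE** — n = 380, uniform 6-option (0–5) format, factor
  correlations 0.79–0.81.  The 6-option reading takes the reported
  0-to-5 response labels at face value; the readers accept any $k \ge 2$,
  so nothing depends on this choice.
* **STUDY34_LIKE** — n = 346, uniform 5-option (0–4) format, 9 reference +
  9 candidate items, factor correlations 0.75–0.81.

Default loadings use the published single-factor estimates for the items
that have them (0.59–0.88) and mid-range values for the rest.  Threshold
layouts follow a survey-design rule: every response category keeps roughly
≥ 5% expected endorsement (all $|\tau| \le 1.65$), so no category is so
rare that its threshold is inestimable at study sample sizes — rare-category
thresholds have marginal standard errors growing like
$1/\varphi(\tau)$, and a layout violating this rule makes finite-sample
recovery noise swamp any estimator.  The latent trait is standard normal
(recorded in `truth.json`), missingness is optional MCAR (default 0), and
all randomness flows from one integer seed.

The covariate generator produces log-BMI linear in the scalar trait
(slope 0.07, residual SD 0.25 — implying a trait–BMI correlation near
0.27 and a BMI SD near 6.6 kg/m² at a 25.6 kg/m² median) and a
type-2-diabetes indicator with 5.5% base rate and 0.6 log-odds per trait
unit; demographics are drawn from fixed marginals typical of online adult
samples.  What the simulator does **not** reproduce: real demographic joint
distributions, non-normal or skewed trait distributions, informative
missingness, attention-check failures, cross-loadings, or local item
dependence.  Passing tests therefore certify the *pipeline's* correctness
under the model's own assumptions, not robustness of the instrument to
violations of them.

## Numerical choices

* Optimization starts at $\lambda = 0.5$, $\psi = 0.5$; convergence
  $|\Delta F| < 10^{-10}$ within 500 iterations; loadings box-bounded at
  $\pm 0.995$ (a bound hit is a Heywood case and warns); sign
  indeterminacy resolved by anchoring the first loading per factor
  nonnegative.
* Zero-count categories collapse into the adjacent lower category (the
  lowest collapses upward) with a warning and a logged code mapping; an
  item with all mass in one category is degenerate and refused.
* Item pairs need ≥ 10 complete observations; a pair table with all mass
  in one cell clamps $\hat\rho$ to $\pm(1 - 10^{-6})$.
* If the assembled polychoric matrix has an eigenvalue below $10^{-8}$
  (possible under pairwise deletion), eigenvalues are clipped and the
  matrix rescaled to unit diagonal, with a `smoothed` flag.  A duplicated
  item alone does not trigger this: the $\rho$ clamp keeps the smallest
  eigenvalue near $10^{-6}$; the flag `near_singular` marks such pairs.
* Three-factor person locations are the mean of three per-factor EAP
  scores, each computed from that factor's items under a standard-normal
  prior — matching the single-total use of these scales.  Cross-factor
  information is deliberately ignored in each factor's posterior; with
  factor correlations above 0.7 the averaged score tracks the mean trait
  closely (checked against simulation truth in the tests).
* Respondents with no observed items score at the prior mean 0 and are
  flagged rather than dropped.

## Problem sizes used in the checks

Parameter-recovery checks run at n = 2000 (18 items), distributional
checks of the simulator at n = 10⁴ draws, the polychoric identity check at
n = 5000, screening recovery at n = 2000 with 12 engineered candidates,
and the end-to-end extension property at n = 1500 with reference
thresholds confined to [−0.5, 1.5] and candidates supplying thresholds in
[−2.5, −1].  These sizes put Monte-Carlo noise well inside the stated
tolerances while keeping a full run inexpensive.

## Limitations

* No full-information IRT estimation, robust standard errors, or
  modification indices; the package is a refinement pipeline, not a
  general SEM engine.
* Fit indices from the unscaled statistic are internally consistent but
  not comparable to robust-scaled output (see above).
* Sum scoring requires complete responses; z-average scoring tolerates
  missingness but assumes items are scored in a common direction.
* The selection policy is one defensible formalization of a human
  judgment; other tie-break orders are equally defensible and can give
  different—equally minimal—covers.
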