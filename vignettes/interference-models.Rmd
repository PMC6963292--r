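---
title: "Modeling retest effects and anxiety interference with latsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling retest effects and anxiety interference with latsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latsem)
```

## The scientific problem

Repeated administrations of a cognitive ability test produce rising scores —
retest or practice effects. `latsem` implements a longitudinal structural
equation modeling framework for one prominent explanation: *situational test
anxiety* interferes with item responses in early sessions (measurement
bias), and the fading of that interference masquerades as ability gain. The
framework pits this interference hypothesis against the deficit hypothesis
(a genuine negative ability–anxiety correlation without measurement bias)
and relates both to the size of latent retest effects.

The reference study design the package is organized around has seven test
sessions; at each session a person answers 13 dichotomously scored
figural-matrices items (the ability measure) and five 7-point Likert
statements on fear of failure (the state-anxiety measure). All empirical
input is a wide person-by-column table of integer codes
(`w{t}_a{j}` / `w{t}_f{j}` columns; see `read_responses()`).

## Measurement model for ordinal responses

Each observed code is a thresholded normal latent response. For a binary
ability item, a single threshold $\tau_j$ cuts the latent response; for a
$K$-point Likert item, $K-1$ increasing thresholds do. Under the *delta
parameterization* every latent response has unit variance, so thresholds and
loadings live on a standardized scale and residual variances are derived
remainders, never free parameters.

Estimation is two-stage ("moments first"):

1. thresholds from univariate margins, $\hat\tau_c = \Phi^{-1}(\hat F_c)$;
2. a polychoric (tetrachoric) correlation per variable pair, maximizing the
   bivariate-normal likelihood of the contingency table with thresholds held
   at stage-1 values. Estimates are clipped to $\pm 0.999$ and flagged when
   the boundary is hit (tables with empty off-diagonal cells); no continuity
   correction is applied.

The asymptotic covariance of the stacked moment vector — needed for robust
test statistics — is assembled from per-person influence functions of the
pairwise-likelihood estimating equations, with the stage-1 plug-in
correction for thresholds. `latsem` never materializes the full
moment-covariance matrix during fitting: every trace and sandwich quantity
is computed from products with the $n \times m$ score matrix, which keeps
the 126-variable study design (8,176 moments) comfortably inside ordinary
memory.

Bivariate normal rectangle probabilities come from a compiled quadrature
routine (arcsin form for $|\rho| < 0.925$, a graded conditional-probability
quadrature above) with absolute error at the $10^{-15}$ level, verified
against multiprecision integration; this bounds all downstream likelihood
comparisons.

## Fitting: DWLS with robust statistics

For ordinal moment sets the engine minimizes the diagonally weighted least
squares discrepancy
$F = (s - \sigma(\theta))^\top W (s - \sigma(\theta))$, $W$ the inverse
diagonal of the moment covariance. Standard errors use the full sandwich
$(J^\top W J)^{-1} J^\top W \Gamma W J (J^\top W J)^{-1}/n$ and the reported
test statistic is the mean-and-variance adjusted (scaled-and-shifted) form
$aT + b$ with $a = \sqrt{df/\mathrm{tr}[(U\Gamma)^2]}$,
$b = df - a\,\mathrm{tr}(U\Gamma)$, the WLSMV convention. Models containing
only the Likert scale are fitted by normal-theory ML on means and
covariances with Satorra–Bentler mean scaling and sandwich standard errors
(robust ML).

Numerical choices: optimization is Levenberg–Marquardt–damped Gauss–Newton
on an analytic moment Jacobian, with variance-type parameters on the log
scale; convergence requires a gradient norm below $10^{-8}$, with a stall at
the double-precision floor of the objective (below $10^{-6}(1+|F|)$)
accepted as converged and the attained norm recorded. Estimation contains no
randomness: identical inputs give bitwise-identical estimates. Correlations
are not transformed; transient non-positive-definite latent covariance
iterates are harmless for the DWLS objective and the final solution reports
a Heywood flag when an implied residual variance is negative. Nested-model
comparisons use the Satorra–Bentler scaled difference constructed from both
fits' mean-scaling factors, falling back (flagged) to the unscaled
difference when the combined scale factor is non-positive. CFI/TLI use the
conventional independence baseline: all correlations zero, thresholds (or
means and variances) free.

## The model families

- `ability_cfa()` — one correlated latent ability state per wave;
  *configural* (free loadings/thresholds per wave), *weak* (loadings shared
  across waves), *strong* (thresholds also shared; latent means free from
  wave 2). Marker identification fixes the first item's loading, unit
  identification fixes latent variances.
- `sta_cfa()` — anxiety states plus one indicator-specific factor per
  questionnaire item (the same five statements recur every session, so item
  residuals are correlated across waves in a way one extra latent per item
  absorbs).
- `lat_model()` — both measurement models merged, with free cross-construct
  correlations (deficit effects) and *interference loadings*: each ability
  item of wave $t$ also loads on the anxiety state of wave $t$.
- `full_interference_model()` — the LAT model with cross-wave ability
  correlations replaced by the neighbor-change growth curve
  $\eta_k = \eta_1 + \sum_{i=1}^{k-1}\delta_{i+1,i}$, all regressions
  residual-free with unit weights. The difference-variable means are the
  retest effects; with all latent variances fixed at 1 they read as
  Cohen's $d$. Strong ability invariance is required (difference means are
  uninterpretable when thresholds drift), weak anxiety invariance is the
  default.

A design-level guarantee worth stating: the strong-invariant ability CFA
and its neighbor-change re-parameterization have identical degrees of
freedom and identical fitted discrepancy — the growth curve is a bijective
re-coordinatization of the state covariance, not a restriction.

### Identification of interference

Estimating free per-item interference loadings *and* free ability–anxiety
correlations reproduces, in the longitudinal setting, the rotational
indeterminacy known from the cross-sectional anxiety–test model. Loading
invariance across waves anchors most of it, but one genuine flat direction
per latent difference remains if the anxiety states may correlate freely
with the difference variables: a uniform shift in a wave's
$\xi$–$\delta$ correlations is absorbed exactly by that wave's interference
loadings (we verified this by fitting the model to its own implied moments
and recovering a different parameter vector at machine-zero discrepancy, and
by the corresponding null space of the moment Jacobian). The package's
default therefore frees only the correlations between the anxiety states
and the first-wave ability state; deficit correlations for later waves are
delta-method derived quantities. The richer pattern remains available
(`anxiety_ability_corr = "all"`) for use with equality-constrained
interference (`"equal-within-wave"`), the conservative identification
strategy that also works on a fully configural base. A configural base with
*free* interference is rejected outright as unidentified.

## Procedures

- `invariance_ladder()` fits configural → weak (→ strong) in order and
  compares successive rungs with the scaled difference test and the
  CFI-difference rule (a drop larger than 0.01 counts as substantial).
- `interference_reduction()` starts from the full interference model and
  successively fixes the last remaining wave's interference loadings to
  zero. Each step frees the same number of parameters (13 in the reference
  design), so the difference statistics are directly comparable in size
  across steps; the first significant step, counting backwards, marks the
  last wave with detectable anxiety bias. The sequence always runs to
  completion. Tests are two-sided at $\alpha = 0.05$ with no multiplicity
  correction across the sequence — a deliberate mirroring of practice in
  this literature, and a documented caveat.
- `retest_effects()` returns the standardized latent difference means with
  Wald tests, 95% intervals, and tests of successive differences through
  the joint parameter covariance. Under marker identification the means are
  standardized by the difference-variable SDs via the delta method. Two
  exact identities are guaranteed and tested: $d_{k,k-1}$ equals the
  implied mean difference of successive states, and the effects telescope
  to the implied final-minus-first mean.
- `interference_report()` tabulates standardized interference loadings with
  Wald p-values, the shared item thresholds, and per-wave deficit
  correlations.

## The simulator and what the tests show

`sim_scenario()` is the generative mirror of the full interference model:
per person, a joint latent vector (first-wave ability, latent differences,
anxiety states, indicator-specific factors) is drawn from a multivariate
normal assembled from the scenario's correlation blocks; later ability
states are exact unit-weight sums; item latent responses add measurement
residuals whose variances are *derived* to make every latent response
variance 1; codes arise by thresholding. Replicate $r$ of an experiment uses
seed $\text{base} + r$; a scenario plus a seed fully determines the data.

`study_like_scenario()` encodes the reference conditions: 7 × 13 binary +
7 × 5 Likert-7 items, $N = 225$, standardized retest effects
$(0.7, 0.3, 0.2, -0.1, 0, 0)$ that plateau after the fourth session,
negative interference on six items at wave 1 (−0.30 to −0.40), four at wave
2, two at wave 3, none later, item difficulties increasing with position on
an easy test, highly stable anxiety states (latent correlations 0.85),
mildly negative correlations of initial ability with both the latent
changes (−0.3) and the anxiety states (−0.15), and unit latent variances
throughout (matching the estimator's identification, which is what makes
recovery experiments interpretable parameter-for-parameter). Magnitudes are
patterned on, not equal to, the empirical study this design reflects; exact
replication of its tables is not claimed. Two honest limitations of the
default scenario: its loadings are bounded above by the unit-variance
budget across seven accumulating waves, so first-wave internal
consistencies (~0.66) sit below typical empirical values; and the easy
items plus large standardized gains put roughly a third of simulated
persons at the ceiling-filter criteria, more than a real sample would
show. Passing tests therefore demonstrate correctness of the machinery
under the model's own assumptions — multivariate-normal latent structure,
exact invariance, no missingness — not robustness to real-data violations
of them.

Problem sizes used by the test suite and the acceptance script (the
package's own choice of simulation budget): recovery of the full model at
$n = 1000$ with 6–10 replicates; difference-test calibration on a two-wave,
four-item design at $n = 500$ with 200 replicates; detection power for
wave-1-only interference ($\beta = -0.35$ on six items) at $n = 1000$ with
6–8 replicates; equivalence identities on a three-wave, three-item design
at $n = 400$.

## Degenerate inputs and tie-breaks

Empty boundary or interior categories collapse before threshold estimation;
a variable with all mass in one category is a named error. Perfect
association clips at $\pm 0.999$ with a boundary flag, and such a pair's
moment gets a unit fallback weight. Fits that do not converge are flagged
and refused by downstream procedures. Missing cells are errors — the
analysis contract is complete cases, matching the completer-based design
the framework targets; no imputation is offered.

## Known limitations

- No full-information (IRT / marginal maximum likelihood) estimation; the
  two-stage moment route is the point.
- No polyserial correlations, survey weights, multi-group models,
  second-order growth factors, or autoregressive state structures.
- The combined model treats the Likert items as ordinal within one DWLS
  fit; a continuous-ML path for the anxiety scale exists only for the
  standalone anxiety CFA.
- Scaled difference tests use the mean-scaling construction; exact
  agreement with other software's internal trace conventions is not
  promised, only method-level behavior (calibration is verified by
  simulation).
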