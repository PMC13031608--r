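---
title: "Methods: sequential design and active learning for cell-free yield optimization"
author: "cfopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential design and active learning for cell-free yield optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfopt)
```

## The problem

A cell-free biosynthesis reaction — here, the five-enzyme conversion of
L-tyrosine to the flavanone liquiritigenin — has a dozen or more tunable
factors: enzyme loadings (mg/mL), cofactor concentrations (mM), substrate
level, pH, temperature, reaction time and volume. Each wet-lab run is
expensive, the response (product titer, mg/L) is noisy at the level of a
few mg/L, and factors interact. The package implements the standard
escalation a process engineer uses under these constraints:

1. **Two-level screening** (Plackett–Burman) to find which factors matter
   at all.
2. **Steepest ascent** along the fitted first-order direction, to walk out
   of the screening region toward the response-surface ridge.
3. **Surrogate-assisted active learning**: fit an ensemble of regression
   models to all accumulated runs, propose the most promising batch of
   conditions by Bayesian optimization, measure them, retrain, and repeat
   until the yield stabilizes.

Every stage consumes and produces the same currency, an
`experiment_table`: one row per run with natural-unit settings, mean
response, replicate sd and replicate count. The 13-factor screening table,
the 20-run design with measured yields, and the 5-trial ascent path of the
liquiritigenin study ship as read-only fixtures (`load_fixture()`), so all
worked examples run offline.

## Coding convention

All modelling happens in *coded units*: factor value $v$ with low/high
levels $(l, h)$ maps to $x = 2(v - c)/(h - l)$ with center $c = (l+h)/2$,
so the low level is $-1$ and the high level $+1$. The transform is affine
and invertible on the whole real line; `to_coded()`/`to_natural()` are
exact mutual inverses (tested to $10^{-12}$). Coding puts heterogeneous
units (mg/mL, mM, °C, µL) on a common scale, which both the screening
regression and the surrogate features rely on.

## Screening model

The screening fit is ordinary least squares of the response on the coded
design with intercept,

$$y = \beta + \sum_i E_i x_i,$$

with per-factor $t = E_i/\mathrm{se}(E_i)$ and two-sided $p$ from the
Student $t$ distribution on $N - k - 1$ degrees of freedom ($6$ for the
20-run, 13-factor case). On a balanced orthogonal design the OLS slope is
algebraically identical to the classical split-sum effect
$(\sum M_{i+} - \sum M_{i-})/N$ with $N$ the total run count, and the
intercept is the grand mean; the test suite asserts both identities on
every supported design size. The half-difference-of-means reading of the
same contrast is exposed as `effect_diff_means` ($= 2E_i$).

A note on the packaged screening statistics: refitting the packaged
20-run table reproduces the published per-factor $t$- and $p$-values to
their printed precision and the same significant set
{ZmPAL, GmCHS, MsCHR, pH, volume} at $p<0.05$, but the published
coefficients (and intercept 38.54) differ from the OLS values by a
uniform factor of about 0.89 — a rescaling we cannot reconstruct from the
printed tables. The package therefore always reports its own OLS values
and keeps the published numbers as a fixture (`printed_screening()`)
rather than forcing agreement.

Designs are generated from the published cyclic generating rows for 8,
12, 16, 20 and 24 runs (cyclic shifts of the generator plus a closing
all-minus run). Balance and pairwise orthogonality are verified by brute
force in the tests rather than assumed.

## Steepest ascent

The first-order model's gradient in coded space is the coefficient
vector; `ascent_direction()` normalizes its restriction to the chosen
factors to unit length, preserving signs (factors with negative
coefficients are walked downward). Because published ascent tables use
manually rounded, per-factor step sizes whose derivation is not
reconstructible, steps are user-supplied in natural units;
`ascent_steps()` offers the obvious helper (base step × direction
component × half-range, rounded per factor). `ascent_path()` is exactly
affine before rounding — trial $i$ sits at $\mathrm{center} + i\,
\mathrm{step}$ — and `best_trial()` breaks ties toward the lowest index.

## Surrogate ensemble and nested cross-validation

Seven regression families span the usual small-data surrogate zoo:
random forest, RBF-kernel support-vector regression, a single-hidden-layer
perceptron, three gradient-boosted-tree configurations (shallow/slow,
deeper/slower, aggressive — three configurations of one boosted-tree
implementation, registered as distinct families), and Gaussian-process
regression. Features are the coded settings; responses stay in mg/L
(scale-sensitive families standardize internally and invert on predict).
Hyperparameter grids are deliberately small (≤ 4 combinations per family),
sized for datasets of 25–100 runs; the registry is an ordinary named list
and fully pluggable.

Evaluation is nested cross-validation, by default 9 outer and 3 inner
folds: the inner grid search (mean squared error) sees only the outer
training rows, the held-out fold supplies the test metrics — Pearson
correlation (the selection criterion) and $R^2 = 1-\mathrm{SSE}/
\mathrm{SST}$. Fold assignment is a seeded shuffle that never looks at
the responses, so corrupting a held-out fold cannot change the chosen
hyperparameters (asserted by a metamorphic test), and the whole procedure
is bit-reproducible given `(seed, dataset)`. Pearson correlation on
three-point folds is undefined when a fold is constant; such folds are
recorded as `NA` and dropped from the mean.

Three fusions combine the seven bases:

* **Simple averaging** — weights $1/k$.
* **NNLS** — weights minimizing $\lVert Pw - y\rVert^2$ subject to
  $w \ge 0$ (Lawson–Hanson active set; no sum-to-one constraint), checked
  against a dense grid search in the tests.
* **Stacking** — a ridge meta-learner fit on *out-of-fold* base
  predictions, with the penalty chosen by internal cross-validation over
  a $10^{-6}\ldots10^{2}$ grid; the intercept is unpenalized and ties
  resolve to the stronger penalty. The ridge solve is closed-form
  (centered normal equations), which keeps the near-zero-penalty identity
  (single perfect base → weight 1) and the duplicated-column symmetry
  exactly testable.

## Batch proposal

The acquisition is the upper confidence bound
$\alpha(x) = \hat\mu(x) + \kappa\,\hat\sigma(x)$ with $\kappa = 1$ by
default. $\hat\sigma$ is the Gaussian-process posterior standard
deviation when the GP alone is the surrogate, otherwise the spread (sd)
of the seven base-model predictions — a model-agnostic uncertainty that
needs no distributional assumptions. `propose_batch()` scores 2000
candidates per round: the first quarter is a seeded Latin-hypercube
space-filling sample of the coded box, the remainder Gaussian
perturbations (scale annealed 0.3 → 0.05 coded units) around the best
scorer so far, alternating with perturbations around an optional
*incumbent anchor* — the best condition actually observed. The anchor is
a deliberate design choice beyond plain best-scorer refinement: a purely
surrogate-guided search can chase a mis-extrapolating model into the
corners of the box and never test near the incumbent, and alternating
centers removes that failure mode while leaving exploration intact. The
top 12 candidates are returned after a greedy minimum-pairwise-distance
filter (0.05 coded units) so the validated batch contains genuinely
distinct conditions.

On the same reasoning, the loop's default surrogate is the **stacking
fusion** of all seven bases rather than the single CV-selected model:
with 25–60 training points in 13 dimensions, a single selected model
(particularly the perceptron) can extrapolate wildly where data are
absent, and the loop then stalls proposing unproductive extremes. The
CV-selected single model remains available (`ensemble = "none"`), and
`select_best()` is always computed and reported.

## Shapley attribution

Per-prediction attributions use the interventional (marginal-expectation)
value function with the training set as background:
$v(S) = \mathbb{E}_b\,f(x_S, b_{\setminus S})$. For ≤ 12 features
`shapley_exact()` enumerates all $2^d$ subsets, so efficiency
($\mathrm{base} + \sum_i \phi_i = f(x)$), dummy and symmetry hold
exactly; above that, `shapley_sampled()` is the permutation estimator
with antithetic ordering pairs (each sampled permutation also used
reversed), seeded and reporting per-feature Monte-Carlo standard errors.
`shapley_summary()` (mean |contribution|, rank, correlation between
feature value and contribution) and `waterfall_data()` (cumulative path
from base value to prediction, largest |contribution| first) provide the
tabular analogues of the usual summary and waterfall displays; plotting
is left downstream.

## The synthetic oracle

The oracle is a test harness emulating the qualitative shape of the
liquiritigenin system, *not* a kinetic model. In optimum-centered scaled
coordinates $u_i = (x_i - x^*_i)/\mathrm{halfrange}_i$ the noiseless
yield is

$$y(x) = y_{\max} + \sum_i q_i u_i^2 + \tfrac12 u^\top B u,$$

with $q_i \le 0$ (concavity enforced at configuration) and a small
symmetric interaction matrix $B$, multiplied by a logistic collapse term
per inhibition rule and clipped at zero. Defaults, fixed before any loop
experiment and treated as the study conditions:

* the 13 screening factors, with bounds widened to the region explored by
  the ascent trials and the final optimized condition, so the optimum is
  interior;
* optimum at the final optimized condition (ZmPAL 4 mg/mL, At4CL4 1.2,
  GmCHS 1.3, MsCHR 3, ZmCHI 1.5 mg/mL; ATP 2.2, CoA 1.2, NADPH 2.4,
  tyrosine 2 mM; pH 7.3; 39 °C; 30 h; 108 µL), maximum 155 mg/L;
* substrate inhibition: above 6 mM tyrosine the yield collapses by 97%
  (logistic steepness 3 /mM), reproducing the near-undetectable product
  seen at high substrate;
* replicate noise 3 mg/L additive plus 5% CV, three replicates — the
  magnitude of the published ± values;
* curvatures chosen so the screening region yields ≈ 15–80 mg/L, the
  range of the published 20-run table, with main-effect signs in the
  screening region matching the published screen (enzyme and volume up,
  substrate and CHS down).

The temperature optimum follows the final optimized condition (39 °C)
rather than the one-factor-at-a-time peak (37 °C); a joint optimum need
not coincide with univariate peaks, and the two differ by less than the
landscape's curvature scale. The noise stream is private to the oracle
and keyed by (config seed, query index): identical query sequences give
identical data, and querying never perturbs the caller's RNG.

What the oracle does *not* emulate: mechanistic enzyme kinetics,
time-course behaviour, heteroscedasticity beyond the CV term, batch
effects, or drift between lab sessions. Passing the closed-loop tests
therefore demonstrates that the machinery can recover a smooth, concave,
mildly interacting optimum from realistic noise and a biased start — not
that it would match any particular wet-lab system.

## The closed loop

`run_loop()` iterates: nested CV → surrogate fit → batch proposal →
responder → append → update best-so-far. The responder abstraction keeps
the loop lab-agnostic: `oracle_responder()` answers from the synthetic
landscape; a real-lab responder would write the batch as a CSV lab sheet
and block until the filled sheet returns. Synthetic initialization
mirrors the study's seeding — a 20-run screen at the screening levels
plus the 5 ascent trials, 25 runs in all. Convergence is declared when
the relative improvement of the best-so-far response stays below 2% for
2 consecutive rounds (10 rounds maximum); the published loop stopped
after three rounds on a qualitative stability criterion. Per-round seeds
derive deterministically from (master seed, round index), and round
states persist as JSON with 17 significant digits, so a crash-resumed
loop is bit-identical to an uninterrupted one.

## Numerical choices and tie-breaks

* Model selection: argmax of mean outer-fold correlation, ties to
  registry order. Consensus hyperparameters for the final refit: most
  frequent per-fold choice, ties to grid order.
* `best_trial()` ties: lowest index. Significance ordering: original
  factor order.
* NNLS rejects an all-zero prediction matrix; the screening fit rejects
  rank-deficient designs; the ascent direction errors on an all-zero
  coefficient vector rather than returning NaN.
* Oracle draws are clipped at zero (yields are concentrations);
  out-of-bounds queries are clipped to bounds with a logged warning.

## Problem sizes used by the shipped checks

The packaged validation uses the sizes of the original study where they
are cheap (20-run screen, 5-trial ascent, 2000-iteration search, batch
of 12, 10 000 sampled permutations against exact enumeration) and scales
the closed-loop replication to 10 seeded runs of 3 rounds each — about
two and a half minutes on one CPU — which is enough to place the median
recovery well clear of the 90% criterion. Unit tests use 2-to-5-factor
spaces and 12-to-27-row tables throughout.

## Known limitations

* The published coefficient rescale (×0.89) is unexplained; conclusions
  that depend on absolute coefficient magnitudes should use the
  package's OLS refit, not the printed fixture.
* With ~25 points in 13 dimensions every surrogate extrapolates poorly;
  the stacking default and incumbent anchor mitigate but do not remove
  this, and single-model surrogates (`ensemble = "none"`) should be used
  with a larger dataset or a narrower space.
* The sampled Shapley estimator's error is reported as a Monte-Carlo
  standard error per feature; for strongly interacting models at small
  permutation budgets this can understate the deviation from exact
  enumeration.
* The loop assumes a stationary landscape; it has no mechanism for
  batch-to-batch drift or replicate-level modelling beyond the mean/sd
  summary.
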