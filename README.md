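# cfopt

Active-learning optimization of multi-factor cell-free biosynthesis
reactions.

Cell-free enzymatic production systems — the motivating case is a
five-enzyme cascade converting L-tyrosine to the flavanone
liquiritigenin — expose a dozen or more tunable factors (enzyme loadings,
cofactors, substrate, pH, temperature, time, volume) and pay for every
experiment in bench time and reagents. `cfopt` implements the standard
sequential-design escalation for such systems, end to end and fully
seeded:

* **Plackett–Burman screening** — cyclic-generator two-level designs for
  8–24 runs; first-order coded-model regression
  `y = β + Σ Eᵢxᵢ` with per-factor *t*/*p* statistics, where the coded
  slope equals the classical split-sum effect `(ΣMᵢ₊ − ΣMᵢ₋)/N` on any
  balanced orthogonal design.
* **Steepest ascent** — unit direction along the fitted gradient, affine
  trial paths with per-factor rounding, best-trial selection.
* **Surrogate ensembles** — seven regression families (random forest,
  RBF-SVM, perceptron, three boosted-tree configurations,
  Gaussian process) tuned and scored by nested cross-validation (9 outer
  / 3 inner folds, selection by held-out Pearson correlation), fused by
  simple averaging, non-negative least squares, or stacking with a
  ridge meta-learner on out-of-fold predictions.
* **Batch Bayesian optimization** — upper-confidence-bound acquisition
  (`mean + κ·sd`), 2000-candidate seeded search (Latin-hypercube
  space-filling, then annealed local refinement), top-12 batch after a
  minimum-distance diversity filter.
* **Shapley attribution** — exact subset enumeration up to 12 features,
  antithetic permutation sampling beyond; summary and waterfall data
  structures.
* **A synthetic yield oracle** — a concave, interacting, noise-bearing
  13-factor landscape with substrate inhibition, standing in for the wet
  lab so the whole loop is testable offline.
* **The closed loop** — screen + ascent seed data, then
  train → propose → validate → retrain until the yield stabilizes, with
  JSON round-state persistence and crash-safe resume.

The screening table, 20-run design with measured yields, and 5-trial
ascent path of the liquiritigenin study ship as plain-text fixtures
(`load_fixture()`), so every example below runs without network or lab.

## Worked example

Refit the packaged 20-run screen, walk the ascent path, then run three
rounds of the active-learning loop against the synthetic landscape:

```r
library(cfopt)

runs <- load_fixture("pb_runs")
fit  <- pb_screen(as.matrix(table_settings(runs)), runs$response)
fit
#> First-order screening fit: intercept 43.29 mg/L, 13 factors, df = 6
#>             coefficient t_value p_value significant
#> ZmPAL             9.378   2.917  0.0267           *
#> At4CL4           -2.808  -0.874  0.4159
#> GmCHS            -9.846  -3.063  0.0221           *
#> MsCHR             8.555   2.661  0.0375           *
#> ZmCHI            -5.258  -1.636  0.1530
#> CoA               4.479   1.393  0.2129
#> ATP               0.847   0.264  0.8010
#> NADPH            -6.551  -2.038  0.0877
#> tyrosine          6.434   2.002  0.0922
#> pH                7.939   2.470  0.0485           *
#> temperature       6.401   1.991  0.0935
#> time             -1.978  -0.615  0.5609
#> volume            9.729   3.027  0.0232           *
#> '*' p < 0.05
```

Five factors pass the 5% screen — the two key enzymes to raise (ZmPAL,
MsCHR), one to lower (GmCHS), plus pH and reaction volume. The *t*- and
*p*-values reproduce the published analysis at printed precision (the
published coefficients differ by a uniform scale factor; see the methods
vignette). The ascent direction and the published path's best trial:

```r
ascent_direction(printed_screening(),
                 c("ZmPAL", "GmCHS", "MsCHR", "pH", "volume"))
#>  ZmPAL  GmCHS  MsCHR     pH volume
#>  0.460 -0.483  0.420  0.389  0.477
best_trial(load_fixture("ascent_trials"))[c("index", "response")]
#> $index
#> [1] 3
#> $response
#> [1] 104.42
```

Yield climbs from 79.6 mg/L (best screening run) to 104.4 mg/L at the
third ascent trial, then falls again — the path has crossed the ridge.
From there the closed loop takes over:

```r
orc  <- make_oracle(oracle_config())        # synthetic stand-in lab
init <- initial_synthetic_data(orc)         # 20-run screen + 5 ascent trials
lc   <- loop_config(space = default_bounds_space(), seed = 1)
st   <- run_loop(init, lc, oracle_responder(orc), max_rounds = 3)
st
#> Round 3: 61 cumulative runs, best-so-far 149.43 mg/L
true_optimum(orc)$yield
#> [1] 154.9991
```

Three rounds of twelve validated conditions lift the best observed yield
from 119 mg/L (in the seed data) to 149.4 mg/L — 96.4% of the
landscape's true 155 mg/L optimum — from 61 experiments total.

## Package layout

* `R/` — factor spaces and experiment tables, screening designs and
  regression, ascent paths, model registry, nested CV and ensembles,
  batch proposal, Shapley attribution, the oracle, the loop.
* `inst/extdata/` — the published screening/ascent tables and the
  printed-yield ledger, as CSV/JSON.
* `vignettes/cfopt-methods.Rmd` — the models, their assumptions, all
  tunable parameters with defaults and rationale, numerical choices,
  what the synthetic landscape does and does not emulate, and known
  limitations.
* `tests/testthat/` — unit, property and acceptance suites (oracle
  checks are independent re-implementations: split-sum effects, dense
  NNLS grid search, subset enumeration, multi-start maximization).
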