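# shapeconv

Quantifying evolutionary convergence in 3D landmark shape data, and
attributing it to ecological and behavioural variables.

## The problem

When distantly related species adapt to the same lifestyle, parts of their
anatomy can evolve to become more similar than their phylogenetic distance
predicts — evolutionary convergence. Detecting that signal in a highly
multivariate structure such as the bony labyrinth of the inner ear (three
semicircular canals, the common crus, the cochlea and the vestibular
windows, captured as 13 anatomical landmarks plus 111 curve semilandmarks
per species) requires a chain of geometric-morphometric and phylogenetic
comparative methods. `shapeconv` implements that chain end to end for
researchers studying convergence in landmark data:

1. **Superimposition** — Generalised Procrustes Analysis (GPA) with
   mirroring allowed (samples mix left and right sides), and semilandmark
   sliding that minimises thin-plate-spline bending energy with a damped
   step (default damping 0.1) so that strongly varying curves such as the
   cochlear spiral slide stably.
2. **Convergence in distances** — all pairwise Procrustes distances are
   split into four pair types: (1) focal species vs their designated
   ecological *analogues*, (2) focal vs non-analogue species, (3)
   focal–focal, (4) nonfocal–nonfocal. Convergence shows as type-1
   distances being smallest; the excess of (2) over (1),
   `100·(d̄₂/d̄₁ − 1)`, is tested by permuting the affiliation of
   non-focal species across analogue pairs. The Wheatsheaf index
   (all-pairs mean over analogue-pair mean, with distances divided by
   their expected Brownian-motion divergence `√(Cᵢᵢ+Cⱼⱼ−2Cᵢⱼ)`)
   summarises convergence strength while correcting for relatedness.
3. **Attribution** — two-block partial least squares (2B-PLS) between the
   `3k` Procrustes shape coordinates and 12 standardised contextual
   variables (body mass + 11 ordinal scores of habitat, locomotion,
   agility and posture): the singular decomposition of the cross-block
   covariance yields paired axes of maximal covariance, with hierarchical
   permutation tests per dimension, a PGLS-based phylogenetic 2B-PLS
   (`R = X₀ᵀC⁻¹Y₀/(n−1)` with GLS-centred blocks), and Blomberg's *K* for
   the phylogenetic signal of each axis.
4. **Subspace contrast** — the leading PLS shape dimensions span an
   "adaptive subspace"; projecting it out and re-running the distance
   comparison inside vs outside shows whether those axes capture the
   convergence signal (squared distances decompose exactly by Pythagoras).
5. **Stability** — leave-one-out, leave-two-out and leave-pair-out
   re-analysis of the distance contrast and PLS.

A first-class synthetic-study generator (`simulate_study()`) produces
labyrinth-like landmark templates, a two-clade ultrametric tree,
Brownian-motion shape evolution with planted convergent regimes, a matching
context table and analogue pairing — with full ground truth, so every
downstream stage can be validated against known answers.

## Worked example

```r
library(shapeconv)

study    <- simulate_study(simulation_config(seed = 42, n_species = 20,
                                             n_focal = 10))
analysis <- run_full_analysis(study, slide = FALSE, n_perm = 999)
print(analysis)
```

```
== Convergence analysis ==
Generalised Procrustes Analysis: 20 configurations, 124 points
  iterations: 2 (converged)
  mirroring: allowed | reflected specimens: 13
Convergence report
  mean distances: analogue 0.0274 | nonanalogue 0.06717 | within-focal 0.05813 | within-nonfocal 0.06
  excess of nonanalogue over analogue pairs: 145.2% (p = 0.001)
  Wheatsheaf index: 2.674 (uncorrected 2.174)
Two-block PLS
  dim 1: singular value 0.04755, 73.0% of squared covariance, p = 0.011
  dim 2: singular value 0.02546, 20.9% of squared covariance, p = 0.001
  dim 3: singular value 0.0102, 3.4% of squared covariance, p = 0.048
  dim 4: singular value 0.005379, 0.9% of squared covariance, p = 0.048
  ...
  Blomberg's K (shape scores): 0.15 0.31 2.07 1.21
  subspace contrast: within excess 225.7%, residual excess -11.2% (p = 0.996)
```

Reading the output: analogue pairs are far closer in shape (mean Procrustes
distance 0.027) than non-analogue pairs (0.067), an excess of 145% that no
affiliation permutation matched (p = 0.001) — the planted convergence is
detected. The first two PLS dimensions carry 94% of the squared cross-block
covariance (the two planted ecological regimes); their shape scores have low
phylogenetic signal (K of 0.15 and 0.31), as expected for convergent axes.
Removing the four leading PLS dimensions removes the convergence signal
entirely (residual excess −11%, p ≈ 1): the adaptive subspace captures it.

Every result object is tidyverse-friendly:

```r
tidy(analysis)                 # one row per PLS dimension with K values
glance(analysis)               # one-row summary of the whole analysis
tidy(analysis$convergence)     # four pair-type averages
autoplot(analysis$pls)         # paired score scatter, ggplot2
leave_k_out(study, mode = "loo", slide = FALSE)   # stability replicates
```

External data come in through `read_landmarks()` (long CSV, one row per
point), `read_context_table()`, `read_pairing()` and `read_newick()`, and
the whole analysis serialises to JSON with `write_analysis_report()`.

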