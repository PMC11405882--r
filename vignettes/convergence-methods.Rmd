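---
title: "Measuring evolutionary convergence in landmark shape data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring evolutionary convergence in landmark shape data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shapeconv)
```

This vignette documents the statistical model behind `shapeconv`, the
choices made where the methodology is genuinely open, and what the
package's synthetic validation does and does not establish about real
data.

## The data model

A study consists of four linked inputs:

* **Landmark configurations** — one per species, 124 ordered 3D points
  under the default scheme: 13 anatomical landmarks and 111 semilandmarks
  on six curves (anterior, posterior and lateral semicircular canals with
  20 each, the common crus with 5, the cochlear spiral with 40, and the
  closed oval-window outline with 6). Units are whatever the scanner
  produced; all scale is removed during superimposition, with centroid
  sizes retained as metadata.
* **Context table** — 12 variables per species: body mass in grams
  (continuous) and 11 ordinal scores (pursuit of prey, aquatic 1–4,
  ground-dwelling, arboreal, scansorial, cursorial, leaping, fossorial,
  moves-3D — all 1–3, agility 1–6, posture 1–5). Ordinal scores are
  treated as numeric; no polychoric or monotone-transform machinery is
  applied.
* **Ultrametric phylogeny** — branch lengths in time; published time
  trees are ultrametric only to rounding, so ultrametricity is checked at
  a relative tolerance of 1e-6 on root-to-tip depths.
* **Analogue pairing** — an a-priori mapping from each focal-clade
  species to the non-focal species designated as its ecological
  analogues. Many-to-many mappings are allowed; a focal species with no
  analogue participates only in the pair types that do not require one.

## Superimposition

Generalised Procrustes Analysis removes location, scale and orientation:
configurations are centred, scaled to unit centroid size, and rotated to
an evolving consensus until the consensus stabilises (RMS change below
1e-9). Reflection is allowed by default because samples mix left and
right body sides; whether a specimen was mirrored is decided at its first
alignment to the consensus and recorded. The consensus is stored as the
plain coordinate-wise mean of the aligned configurations, so the
invariant `consensus == mean(aligned)` holds exactly rather than up to a
renormalisation.

The Procrustes distance reported everywhere is the *partial* Procrustes
distance: the Euclidean norm of the difference between two aligned,
unit-size coordinate rows in the common superimposition. With a single
joint alignment this is the natural "distance between all pairs"; the
full (chord) variant would differ only in the third decimal for shapes
this similar and is not exposed.

### Semilandmark sliding

Semilandmarks are slid along their curves to minimise the thin-plate-
spline bending energy of the deformation from the reference. Numerical
choices, all overridable:

* **Kernel** — the 3D TPS kernel `U(r) = −r`, so the bending-energy
  matrix (the upper-left block of the inverted TPS system) is positive
  semidefinite and vanishes exactly on affine displacement fields.
* **Tangents** — estimated per iteration by central differences of each
  point's curve neighbours (forward/backward at open ends; wrapping on
  the closed oval-window outline). Anchors — anatomical landmarks and
  the free cochlear base — never move.
* **Damping** — each iteration computes the exact minimising step along
  the current tangents and applies a fraction 0.1 of it. A damped step on
  a convex quadratic always descends, so bending energy decreases
  monotonically even though tangents are re-estimated between steps;
  curves with extreme variation (cochlear coiling) stay stable at the
  cost of more iterations. Damping changes the path, not the optimum, on
  convex cases.
* **Reference** — the evolving GPA consensus, alternating slide and GPA
  passes until the consensus stabilises (default at most 10 alternations,
  tolerance 1e-6). The reference choice is a genuine methodological
  opening; the consensus is the reproducible standard choice.

## Convergence statistics

All unordered species pairs are partitioned into four disjoint types —
focal–analogue, focal–non-analogue, focal–focal, nonfocal–nonfocal — and
mean (and median) distances are compared. The headline statistic is the
excess of non-analogue over analogue means, `100·(d̄₂/d̄₁ − 1)`, which is
invariant to global rescaling of the distances.

The permutation test permutes the *affiliation* of non-focal species
across analogue pairs: the non-focal labels are randomly relabelled among
themselves, which preserves every focal species' analogue count and the
pairing's cardinalities while breaking the claimed ecological match. The
test is one-sided in the convergence direction by default (the hypothesis
is directional); p-values use the `(b+1)/(N+1)` estimator, so they are
never exactly zero.

The Wheatsheaf index is reported in the convergence-positive orientation:
the mean distance of a comparison set (all pairs by default, optionally
non-analogue pairs) divided by the mean analogue-pair distance, so values
above 1 indicate convergence. The corrected form divides each pairwise
distance by the pair's expected Brownian divergence
`√(Cᵢᵢ + Cⱼⱼ − 2Cᵢⱼ)`, normalised to mean 1 so the correction changes
relative weights only. The exact penalty function behind published
variants of this index differs between implementations; this one is the
simplest choice that (a) reduces to the uncorrected ratio on a star
phylogeny and (b) down-weights similarity that mere relatedness would
predict.

## PLS and phylogenetic signal

Contextual variables are mean-centred and scaled to unit *sample*
variance (denominator `n−1`, used consistently for all covariances in the
package); body mass is natural-log transformed first by default because
it spans orders of magnitude and would otherwise dominate as a leverage
point. Two-block PLS is the singular decomposition of the cross-block
sample covariance of the centred blocks; each dimension's share of the
summed squared covariance is `σₖ²/Σσ²·100`. Signs are fixed by orienting
each dimension so its largest-magnitude context loading is positive,
making output deterministic across platforms.

The hierarchical permutation test evaluates dimension *k* conditional on
the lower dimensions: both blocks are deflated of the first `k−1`
observed singular-vector pairs, the rows of the deflated context block
are permuted, and the statistic is the leading singular value of the
deflated cross-covariance. "Hierarchical" schemes are not uniquely
defined in the literature; this conditional reading is the one under
which dimension 1's test is the classic overall PLS permutation test.

**Calibration caveat.** A row-permutation test is exact only when one
block's rows are exchangeable. When both blocks carry strong phylogenetic
signal, independent traits still produce systematic cross-covariance
(closely related species resemble each other in both blocks), and the
test rejects far above nominal — the package's own null simulations
demonstrate this, and it is precisely the motivation for the phylogenetic
PLS. The calibration suite therefore checks the test's level under an
exchangeable null (no Brownian shape structure), checks the convergence
permutation test under the full Brownian null with no planted effect
(where analogue and non-analogue pairs both span the basal split and have
identical distance distributions), and provides `phylogenetic_two_block_pls()`
— the GLS cross-covariance `X₀ᵀC⁻¹Y₀/(n−1)` with GLS-centred blocks — for
inference that accounts for the tree. Species scores of the phylogenetic
PLS project the ordinary centred blocks onto the evolutionary singular
vectors (the usual plotting convention); projecting the whitened blocks
instead is a flag.

Blomberg's *K* is computed from its closed form with the GLS mean: the
ratio of observed to GLS mean-squared error, scaled by its Brownian
expectation. *K* is exactly 1 on a star phylogeny, averages 1 for
Brownian traits on any tree (verified by simulation), is below 1 for
convergent axes, and is invariant to affine transforms of the trait.

## The adaptive-subspace contrast

The leading PLS shape loadings (default 4) span the "adaptive subspace".
Because the loadings are orthonormal, squared pairwise distances
decompose exactly into a within-subspace part (distances between score
vectors) and a residual part (distances after projecting the subspace
out). Re-running the pair-type contrast on both parts shows where the
convergence signal lives. With `n_dims_adaptive = 0` the residual
contrast is by construction identical to the full one.

## What the synthetic generator emulates

`simulate_study()` generates the full data model with known truth:

* **Template** — a parametric labyrinth-like configuration: three
  mutually oblique near-circular canals, a common crus joining two of
  them, a conical cochlear spiral with a configurable number of turns,
  and an elliptical oval window. It is smooth synthetic geometry, not a
  measured specimen.
* **Tree** — a unit-depth basal split joining two pure-birth clades: the
  focal clade (stem 0.4, so it is phylogenetically coherent) and the
  analogue pool (stem 0.05, so analogues scatter across the tree, as
  ecological analogues drawn from a whole class do).
* **Shapes** — template + Brownian deviations along the tree +
  `effect·regime_score·loading` per planted regime + digitising noise,
  then a random similarity motion (and mirroring for left-sided
  specimens) per species. Magnitudes are fractions of template centroid
  size: Brownian tip dispersion 2%, planted displacements
  `8%·0.6^(r−1)` (distinct strengths keep successive singular values
  separated, as in real data where one ecological contrast dominates),
  noise 0.4%. Brownian motion acts on raw coordinates, not tangent-space
  coordinates, because downstream GPA is part of the system under test;
  at 2% dispersion the small-variation (tangent) regime holds.
* **Regimes, context, pairing** — regimes occupy contiguous blocks of
  the focal clade and randomly scattered non-focal species (guaranteeing
  at least two cross-clade analogue pairs); each regime drives one
  designated ordinal variable (latent score + Gaussian noise, thresholded
  to the variable's level range, then misclassified at rate 0.1);
  remaining ordinals are half-heritable (Brownian latent plus independent
  noise), and log body mass evolves by Brownian motion. The pairing maps
  focal regime members to the non-focal members of their regime; focal
  species without a regime are unpaired, mirroring a focal taxon with no
  living analogue.

What it does **not** emulate: biomechanically realistic labyrinth
geometry, Ornstein–Uhlenbeck or multi-rate evolution, within-species
variation, measurement correlation along curves, or fossil taxa. Passing
the synthetic validation therefore shows that the estimators and tests
are correct and well calibrated under a Brownian-plus-displacement world;
it does not certify the biological model for any particular empirical
dataset.

One subtlety the generator exposes: planted loadings live in raw
coordinate space, and semilandmark sliding deliberately discards the
tangential component of variation. Sliding therefore *lowers* the vector
correlation between recovered and planted axes even while improving the
correspondence of the points; recovery is measured on the unslid
alignment, and the slid value is reported alongside it.

## Problem sizes and reproducibility

All stochastic steps consume substreams derived from one master seed
(31-bit linear-congruential mixing), so identical configurations
reproduce reports byte for byte and replicates are independent of
execution order. The validation suite uses 500 null replicates at 12
species and 199 permutations for test calibration, 100 replicates at the
default 40 species for recovery/power, and 1000 Brownian traits on a
fixed 40-tip tree for the *K* sanity check; these sizes give binomial
confidence intervals narrow enough for the stated bounds while keeping
the suite quick on a single CPU.

## Known limitations

* Exactly one specimen per species; duplicate species are rejected
  rather than averaged.
* Missing landmarks and missing context values are not estimated.
* The ordinal context variables are treated as interval-scaled scores.
* The hierarchical test's deflation scheme is one of several defensible
  readings of "hierarchical"; p-values for dimensions beyond the first
  are approximate in that sense.
* Surface (patch) semilandmarks and minimised-Procrustes-distance
  sliding are out of scope; sliding is bending-energy only.
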