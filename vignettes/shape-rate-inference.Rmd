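---
title: "Comparing multivariate rates of body-shape evolution between clades and modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multivariate rates of body-shape evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaperates)
```

## The model

Body shape is summarized by k = 18 two-dimensional landmarks per
specimen. After generalized Procrustes superimposition and per-species
averaging, each species is a point `y_i` in a p = 2k dimensional trait
space. Evolution is modeled as multivariate Brownian motion on a
time-calibrated, ultrametric phylogeny: trait variance accumulates
linearly with time, so the among-species covariance of any one trait is
`sigma2 * C`, where `C[i, j]` is the shared path length (Myr) from the
root to the most recent common ancestor of species i and j.

The net rate estimator whitens the data by the phylogeny. With
`a = (1'C^-1 1)^-1 1'C^-1 Y` the GLS estimate of the root state and
`Yt = C^(-1/2)(Y - 1a')` (symmetric eigendecomposition square root),
the rate for a species group g is

    sigma2_g = sum_{i in g} ||Yt_i||^2 / (N_g * p)

and the pooled rate uses all n species. Dividing by `N * p` makes
rates *per trait* per Myr, so values are comparable between modules
with different landmark counts; every reported ratio is invariant to
this normalization choice. For p = 1 the estimator is the familiar
Brownian-motion ML rate, including its `(n-1)/n` finite-sample factor.

Two whitening properties the tests rely on: the transform acts on rows
(species) only, so restricting to a column subset (a landmark module)
before or after whitening is identical; and rates estimated on a tree
with all branch lengths multiplied by c are exactly the original rates
divided by c, leaving ratios and p-values unchanged.

## Hypothesis tests

Three tests share one machinery:

1. **Clade rate ratio** (`rate_ratio_test`): observed statistic
   `max(sigma2_A, sigma2_B) / min(...)` over the two clades.
2. **Module rate ratio** (`modularity_rate_test`): the same statistic
   over landmark modules (head: 1–8, 15–18; trunk: 9–14), computed
   tree-wide.
3. **Clade ratio within a module** (`within_module_clade_test`):
   test 1 on the module's columns; with the full landmark set and the
   same seed it reproduces test 1 exactly.

Significance comes from parametric simulation under the null of one
shared rate: `nsim` datasets are drawn as matrix-normal tip data with
row covariance `C` and a common trait (rate) matrix, each re-processed
through the identical whiten/estimate/ratio pipeline, and

    p = (1 + #{simulated ratio >= observed}) / (1 + nsim)

so p is never zero and the observed data count as one draw. `nsim`
defaults to 9999; tests in this package use smaller values for speed.

### The null rate matrix, and why it is shrunk

Simulating the null with an isotropic rate matrix (`sigma2 * I`) is
wrong for Procrustes data, whose traits are correlated and occupy at
most `2k - 4` dimensions: the effective trait dimension controls the
spread of the ratio statistic. The default therefore uses the
among-trait covariance of the whitened residuals. But the raw p x p
sample covariance from only n rows (36 traits from 44 species) has
strongly overdispersed eigenvalues, which makes the simulated ratios
too variable and the test conservative — measured rejection rate 8/500
at alpha = 0.05 before correction. The package applies Ledoit–Wolf
shrinkage toward sphericity (intensity estimated from the data, here
typically large under near-spherical truth, small under strong
correlation), then rescales so the mean diagonal equals the pooled
rate. After shrinkage both tests reject at the nominal rate (19/500
and 22/500 in the acceptance suite). An isotropic null remains
available (`null_cov = "isotropic"`).

For the module test, the observed module imbalance must not leak into
the null: the whitened *columns* of each module are first rescaled to
the common per-trait rate, and the null covariance is estimated from
those rescaled residuals. (Rescaling the covariance matrix after
shrinkage instead would invert the observed imbalance into the null —
a bug the type-I simulations caught at 0/500 rejections.)

## Procrustes superimposition choices

* Full Procrustes: centering, unit centroid size, iterative rotation
  to the evolving consensus; rotations are constrained to det = +1
  because all specimens are digitized from the same (left-lateral)
  side, so a reflection indicates a data error, not biology.
* The first configuration initializes the consensus; convergence when
  the root summed squared consensus change drops below `tol = 1e-8`
  (max 100 iterations; non-convergence is reported, not fatal). The
  final orientation is the consensus' principal axes with a
  deterministic sign convention, so output is reproducible across
  input orders and platforms up to ~1e-7.
* The reported consensus is the arithmetic mean of the aligned
  configurations (the unit-rescaled mean is only the iteration
  reference).
* **Sphere vs. tangent space.** Unit-size Procrustes coordinates live
  on a sphere, so the scale dimension is removed only to first order:
  with digitizing noise of 1% of centroid size, the covariance
  eigenvalue beyond rank `2k - 4` is ~1e-4 of the largest, not zero.
  Exact rank `2k - 4` holds after orthogonal projection onto the
  tangent space at the consensus (`project_tangent = TRUE`), at the
  price of centroid sizes deviating from 1 by O(noise^2). The two
  idealizations are mutually exclusive beyond first order; the package
  defaults to the sphere (no projection), and the test suite asserts
  each invariant in the coordinate system where it is exact. At these
  noise levels the rate statistics differ negligibly between the two.

Species means are taken *after* one joint GPA over all specimens of
both clades — aligning clades separately would confound the contrast
with alignment differences. GLS mean and whitening likewise use the
full tree once; group rates partition the whitened rows rather than
re-transforming per group.

## The synthetic-data generator

`generate_chronogram()` builds the stated study world: two clades of
40 and 4 species joined 18.02 Myr ago, within-clade topologies and
node heights drawn from a seeded Yule (pure-birth) process — the tree
prior behind the published chronogram — rescaled to crown ages of
14.05 and 6.88 Myr (the published divergence-date estimates for the
corresponding clades). Split ages are floored at 0.25 Myr: random
branching processes produce arbitrarily recent splits that real
species-level chronograms lack, and such near-zero branches amplify
finite-specimen measurement noise under whitening (the contrast
between two species carries a `noise_variance / branch_length` term
that the Brownian model does not account for; an unfloored generator
occasionally inflated a clade's rate severalfold). `simulate_study()`
then evolves species mean shapes by Brownian motion from an
18-landmark fish-like template:

* **Rates.** Defaults: 2e-4 (fast clade) vs. 1e-4 (slow clade) per
  trait per Myr — the ~2x headline contrast — applied by rescaling
  branch lengths per clade. Over 18 Myr this yields between-species
  Procrustes distances of roughly 0.1–0.3, the upper end of realistic
  congeneric fish divergence.
* **Tangent frame.** Brownian deviations are projected orthogonal to
  the template's similarity directions (scale, rotation, x/y
  translation), so simulated means are pure shapes. Consequently the
  realized per-trait rate is exactly `sigma2 * (p - 4)/p`, and the
  truth-recovery test uses that closed form (together with the
  `(n-1)/n` GLS factor) as its expectation.
* **Module contrasts** multiply the per-trait rate of a module's
  columns (before projection).
* **Specimens.** Species mean + isotropic digitizing noise
  (sd = 0.01 centroid-size units; a per-landmark vector is accepted),
  then random rotation, scaling to "digitizer units" (uniform 80–320),
  and translation (±500) before TPS writing — so GPA has real work to
  do. 38 specimens per species by default (~1670 total, the study's
  scale).

Every dataset is a pure function of its `truth_record` (one seed
drives all draws), and the record is serialized beside the data.

**What a green test does and does not establish.** The generator
matches the inference model by construction: Brownian motion, a
correct ultrametric tree, isotropic digitizing noise, no allometry, no
measurement outliers, no within-species structure, and landmark
identity across specimens. Recovery and calibration results therefore
validate the *implementation*, not the robustness of the method to
model violations (unequal specimen counts, non-Brownian evolution,
tree error), which are out of scope here.

Known attenuations worth remembering when reading recovery tests: the
rank deficiency of shape space scales absolute rates by `(p-4)/p`
(~11%), and Procrustes fitting of finite-amplitude deviations
compresses module contrasts — with a true 2.5x trunk multiplier the
median recovered module ratio across 100 full-pipeline replicates is
~2.1 (within the 20% acceptance band). Clade ratios are unaffected to
first order because both clades attenuate equally; the 40-vs-4 design
makes the ratio noisy (IQR roughly 1.9–2.4 around a true 2.0), which
is a property of the study design, not the estimator.

## Numerical and interface choices

* Covariance inversion and square roots use symmetric
  eigendecompositions; eigenvalues below -1e-9 of the maximum are a
  hard PSD error, small negatives are clipped. Singular `C` (duplicate
  zero-length tips) errors rather than pseudo-inverting.
* Non-ultrametric trees (relative depth spread > 1e-6) warn and
  proceed — published chronograms are usually rounded.
* Pruning keeps the shared basal stem (as a root edge included in
  every covariance entry), so tip depths are preserved and the pruned
  covariance is exactly a submatrix of the full one.
* Ties in the ratio orientation are broken by the order of group
  labels; the orientation is always reported explicitly.
* PCA signs follow a fixed convention (largest-magnitude loading
  positive), making morphospace plots reproducible. Ancestral states
  are computed on PC scores; by linearity this equals estimating
  ancestral shapes and projecting them, and the tests assert that
  identity.
* All results serialize to JSON with full precision; identical config
  and seed give byte-identical reports. Newick and TPS writers emit
  17 significant digits so read/write round trips are bit-exact.

## Limitations

Two-group and two-module designs only (no omnibus >2-group test); no
Ornstein–Uhlenbeck or early-burst alternatives; no semilandmarks,
sliding, or allometry correction; the 4-species clade makes its rate —
and hence the ratio — high-variance, which the package flags but
cannot fix. Table-style absolute rates depend on the `N * p`
normalization convention and are not comparable across software that
normalizes differently; ratios are.
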