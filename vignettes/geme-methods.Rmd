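---
title: "Measuring weighted-network complexity with geme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring weighted-network complexity with geme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geme)
```

## The problem

Dense weighted networks — functional brain connectivity matrices, stock
co-movement matrices — carry their organization in continuous edge weights
whose joint distribution is unknown and heavily correlated.  Entropy-style
complexity measures built for binary graphs do not transfer: thresholding
the weights discards information, and estimating the weight distribution
directly is intractable.  `geme` instead asks a geometric question: *if the
nodes are placed in a low-dimensional Euclidean space so that distances
reflect connection strength, does the resulting point cloud look organized
or random?*

The answer is a single nonnegative scalar, the Geme score, computed in three
steps.

## The model

**1. Embedding.**  For a symmetric weight matrix $W_{n\times n}$ (typically
correlations, $-1 \le w_{ij} \le 1$), form the double-centered Gram matrix

$$B = \tfrac{1}{2} J W J, \qquad J = I_n - \tfrac{1}{n}\mathbf{1}\mathbf{1}^\top,$$

and factor it: the node coordinates $\tilde X_{k\times n}$ are the top-$k$
eigenvectors of $B$ scaled by the square roots of their eigenvalues, so
$\tilde X^\top \tilde X$ is the best rank-$k$ nonnegative approximation of
$B$ in Frobenius norm.  This is the classical-scaling factorization applied
to a similarity matrix: for a correlation-like $W$ the centered matrix
itself (not its negation) is the near-positive-semidefinite target, and the
global factor $1/2$ merely rescales coordinates.  Negative eigenvalues —
which appear when $W$ is not positive semidefinite, e.g. after adding noise
or a Fisher z transform — are clipped to zero; the clipped mass is recorded
and a warning is raised when it exceeds 5% of total absolute spectral mass.
Because the construction commutes with node permutation and the score uses
only interpoint distances, Geme is invariant across isomorphic networks.

**2. Point-pattern analysis.**  The embedded cloud is compared with complete
spatial randomness (CSR) through Ripley's K function on the axis-aligned
bounding box of the points,

$$\hat K(r) = \hat\lambda^{-1}\frac{1}{n} \sum_i \sum_{j \ne i}
  \eta_{ij}\, \mathbf{1}(d_{ij} < r),$$

with $\hat\lambda = n/|W|$ the empirical intensity and $\eta_{ij}$ an edge
correction for pairs near the window boundary.  The default correction is
the translation correction $\eta_{ij} = |W| / |W \cap (W + x_j - x_i)|$,
which is closed-form for a box in any dimension; the Ripley isotropic
correction is available for $k = 2$ as a cross-check against standard
spatial-statistics references.  A direct transcription of the cross-entropy
curve $L(r) = -\frac{1}{n}\sum_i\sum_{j\neq i} \mathbf 1(d_{ij}<r)\,
\log(\pi r^2 \hat\lambda)$ is exposed as `cross_entropy_direct()` for
inspection; it is not the default path because its $\log(\pi r^2 \lambda)$
factor is $r$-dependent and cannot equal a constant multiple of $K(r)$.

**3. The score.**  With $\hat L(r) = \hat K(r)/c$ and $c = 1$ by default,

$$\widehat{\mathrm{Geme}} = \int \hat L(r)\, dr$$

by the trapezoidal rule over the radii grid.  Clustered clouds accumulate
many close pairs and a large area under $\hat K$; CSR-like clouds track
$\pi r^2$ and score low.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 2 | embedding dimension; 2 keeps the K-function geometry planar and matches the usual demonstration setting; larger `k` works with the translation correction |
| `correction` | `"translation"` | edge-correction weight $\eta_{ij}$; `"none"` for the raw count, `"isotropic2d"` for 2-D cross-checks |
| `n_radii` | 100 | grid resolution; the score is a trapezoidal integral over this grid |
| `r_max` | quarter of the shortest window side | standard Ripley practice limiting boundary bias |
| `c_constant` | 1 | the constant in $L = K/c$; rescales the score only |
| `expand_fraction` | 0 | symmetric expansion of the bounding window, useful when points coincide on an axis |

All units are those of the embedding coordinates (square roots of edge
weight); the score itself is therefore scale-bearing — see the limitations
below.

## The synthetic-data generator

`simulation_spec()` + `simulate_group_study()` emulate a group-level
functional-connectivity study.  Each subject's $n \times T$ signal matrix is
drawn from $N(0, \Sigma)$ where $\Sigma$ is block diagonal: community
blocks of size $a$ with compound symmetry $I_a(1-\rho) + J_a\rho$, identity
elsewhere; the network is the sample correlation matrix of those signals,
computed about the known zero mean ($U = ZZ^\top/(T-1)$, then unit-diagonal
normalization).  Defaults follow the two-group design the package validates
against: $n = 100$ nodes, group one blocks $(20, 30)$ at correlations
$(0.5, 0.6)$, $S_0 = S_1 = 100$ subjects.

$T$ is the one design quantity the source design leaves open; the default
is $T = 150$, a typical resting-state fMRI volume count that makes
$100\times100$ sample correlation matrices well conditioned.  It is exposed
in every spec.

Seed policy: a master seed is folded with (replicate, group, subject) tags
through a fixed modular mixing function, so any single subject is
reproducible in isolation and group substreams never overlap.  The grid
runner `power_grid()` deliberately reuses one master seed across cells
(common random numbers), which sharpens cross-cell power comparisons.

What the generator does **not** emulate: hemodynamic response,
autocorrelated or heavy-tailed noise, motion artifacts, global-signal
effects, or inter-subject variation in block membership.  Tests passing on
this generator show the estimator chain is correct and powerful under the
idealized block-Gaussian design; they do not certify behavior on real fMRI
data.

## Numerical choices

* Strict inequality $d_{ij} < r$ in all indicator sums; coincident points
  count at every positive radius.
* Eigenvalues sorted descending; each eigenvector's sign is fixed so its
  largest-magnitude entry is positive.  Distances are unaffected; the
  convention only makes coordinate output deterministic.  Within a tied
  eigenspace the retained basis is whatever LAPACK returns — distances
  across a truncated tie are then basis-dependent, which is inherent to
  rank truncation, not to this implementation.
* A degenerate spectrum (no positive eigenvalue but some negative mass)
  raises an error; an exactly flat network ($B = 0$) embeds to coincident
  points and is caught at the window stage instead.
* Zero-volume windows (all points coincident on an axis) raise an error
  directing the caller to `expand_fraction` or a smaller `k`.
* Radii beyond half the window diameter warn (boundary bias) but compute.
* `read_adjacency()` accepts asymmetry up to $10^{-8}$ (averaged away) and
  refuses anything larger; output files carry 10 significant digits.

## Design choices made where the design was open

* **Sign of the Gram target.**  The centered similarity $+\frac12 JWJ$ is
  factored directly.  The $-\frac12$ convention of classical scaling applies
  when the input is a squared-distance matrix; for a similarity matrix the
  positive form is the near-PSD object.  Permutation invariance and group
  separation hold under either; the absolute scale differs.
* **$c = 1$.**  The constant relating $L$ and $K$ is not determined by the
  source material (both $L = cK$ and $\hat L = c^{-1}\hat K$ appear); with
  $c = 1$ they coincide and the score is the area under $\hat K$.
* **Window.**  The bounding box of the embedded points, because it makes
  the translation correction closed-form in any dimension.  No external
  window exists since the embedding space has no canonical frame.
* **Two-group test.**  Welch's t-test, robust to the variance inequality
  that different network structures induce; a Wilcoxon rank-sum alternative
  sits behind `method = "wilcoxon"` for sensitivity analysis.
* **Stratified regression.**  `covariate_regression()` fits the final
  interaction model `geme ~ group + sex + age + group:sex` directly;
  automated step-wise model search is intentionally out of scope.

## Known limitations

**The score is scale-bearing.**  Geme integrates $\hat K$, which has units
of window area, over a radius grid proportional to window size: the score
scales cubically with the embedded cloud's linear scale, and that scale
grows with both community size and within-community correlation (top
eigenvalues $\approx a\rho/2$).  Two consequences matter when interpreting
group comparisons:

* Differences in overall correlation *level* move the score strongly, even
  when the community layout is identical.  In the two-group power study,
  lowering group two's correlations from $(0.5, 0.6)$ to $(0.3, 0.2)$ at
  matched block sizes shifts mean Geme by several within-group standard
  deviations, so the comparison rejects essentially always — the metric
  reads a correlation-level change as a complexity change.
* Mean Geme is not monotone in community size at fixed correlations: at the
  package's problem sizes, blocks $(10, 15)$ average a *higher* score than
  $(20, 30)$ (about 0.0246 vs 0.0180 at $T = 150$), because the smaller
  cloud concentrates its pairs within the window-relative radius grid.

Scale-normalized variants (a unit-square window, or the direct
cross-entropy curve whose $\log(\pi r^2\lambda)$ factor is
scale-invariant) were evaluated during development and remain strongly
sensitive to correlation level through the relative tightness of the
embedded clusters; none was adopted as a default.

**Problem sizes used in the shipped checks.**  The package's study-scale
tests run the full grid at 50 replicate studies per cell and the
acceptance script at 100, each replicate simulating 200 subjects of
$100\times150$ signals; smaller unit tests use 8–30 node networks.  CSR
calibration uses 500 uniform patterns of 200 points.

**Other limitations.**  No sparse or out-of-sample embedding; no
inhomogeneous-intensity K functions or pair-correlation functions; no CSR
envelope tests; no neuroimaging file formats — inputs are delimited-text
matrices.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(100, c(20, 30), c(0.5, 0.6), n_subjects = 5, seed = 1)
nets <- lapply(1:5, function(s) correlation_network(sample_timeseries(spec, s)))
geme_batch(nets)

# organized vs marginal-matched random
net <- nets[[1]]
geme(net)$geme
geme(randomize_network(net, seed = 1))$geme

# two tiny groups, end to end
s2 <- simulation_spec(100, c(20, 15), c(0.6, 0.5), n_subjects = 5, seed = 1)
study <- simulate_group_study(spec, s2)
tidy(two_group_test(geme_batch(study$group1)$geme,
                    geme_batch(study$group2)$geme))
```
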