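---
title: "Distance-based analysis of Napping panels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based analysis of Napping panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensmap)
```

## The data and the model

A Napping panel consists of $m$ raters each placing the same $n$ products on
a private two-dimensional sheet.  Because each sheet's coordinate frame is
arbitrary (the rater chooses origin, orientation, and often implicitly a
scale), raw coordinates are not comparable across raters.  Two analysis
routes respect this:

* **Distances first.**  Per rater, the pairwise Euclidean distances
  $d_r(i,j)$ are invariant to rotation, reflection and translation of the
  sheet.  Averaging them over the panel, $\bar d(i,j) = \tfrac1m \sum_r
  d_r(i,j)$, yields a single product dissimilarity matrix — a metric,
  because a mean of metrics is a metric — which feeds hierarchical
  clustering directly, with no projection step and therefore no projection
  loss.
* **Concatenation / MFA.**  Each product is the $2m$-vector of its
  coordinates across raters (the vectors span at most an $n$-dimensional,
  in practice $(n-1)$-dimensional, subspace).  Distances can be taken in
  this space directly (`concatenated_distances()`), or the space can be
  ordinated by Multiple Factor Analysis and interpreted through its leading
  dimensions.

The package implements both so they can be compared on the same panel.  The
clustering route is primary: it uses the products' original
(dis)similarities, while any 2-D MFA map may lose a large share of the
variance — `projection_distortion()` makes that loss explicit.

## Clustering

`agglomerate()` is UPGMA (size-weighted average linkage) via Lance–Williams
updates: after merging $A$ and $B$, $d(A\!\cup\!B, K) = \frac{|A| d(A,K) +
|B| d(B,K)}{|A|+|B|}$, which equals the mean of all cross-cluster product
pair distances.  Average linkage admits no inversions, so merge heights are
non-decreasing; the test suite asserts this on random metric inputs and
checks the whole merge history against a naive recompute-everything oracle
and against `stats::hclust(method = "average")`.

Ties are broken by the lexicographically smallest pair of cluster indices
(leaves first, then merge order), so results are identical across platforms.
The number of clusters is a user decision — typically made on the dendrogram
— and `cut()` demands an explicit `k` or height; `suggest_k()` ranks
candidate cuts by mean silhouette width but is advisory and never
auto-applied, since no cut rule is canonical for sensory data.

Cluster interpretation is descriptive: `descriptor_profile()` counts
descriptor tokens per cluster over all (rater, product) mentions, the
frequency semantics of a word cloud.  Deliberately, there is **no formal
test of descriptors against clusters**: raters use their own verbalizations
when placing products, so that dependence holds by design.
`build_contingency()` refuses factors declared descriptor-derived unless
forced, and the test of record is cluster membership against *external*
design factors (breed, feeding) via the exact test below.

## The exact test

For an $R \times C$ table with both margins fixed, each margin-compatible
table $T$ has multivariate hypergeometric probability
$P(T) = \frac{\prod_i r_i!\, \prod_j c_j!}{N!\, \prod_{ij} t_{ij}!}$, and
the two-sided Freeman–Halton p-value is $\sum_{T:\,P(T) \le P(obs)} P(T)$.
Implementation notes:

* probabilities are computed in log space from `lgamma`;
* enumeration is recursive row-wise cell filling with margin-feasibility
  pruning (each cell ranges over the values that leave the remaining
  margins attainable), with a configurable budget (default $10^7$ tables)
  beyond which the user is pointed at the Monte-Carlo variant;
* the rejection region uses $P(T) \le P(obs)\,(1 + 10^{-7})$: the relative
  tolerance absorbs floating-point ties and is required to reproduce the
  reference worked-example value 0.01587 exactly;
* `freeman_halton_mc()` samples margin-fixed tables by Patefield's
  algorithm (`stats::r2dtable`) and uses the $(1+k)/(B+1)$ estimator.

Exact conditional tests on discrete data are *super-uniform* under the
null ($P(p \le \alpha) \le \alpha$); the acceptance suite verifies this
empirically at three $\alpha$ levels with 2000 margin-fixed replicates.

Multiplicity: `adjust_p()` implements Bonferroni ($\min(1, m\,p)$) and Holm
step-down, with the family size $m$ always supplied by the caller — in the
worked example $m = 3$, the three preparations on which the same analysis
was run.

## MFA

Each rater's two centered coordinate columns form one group.  Groups are
weighted by $1/\sigma_1^{(r)}$ (first singular value of the centered
block), equalizing the groups' possible contribution to the first global
dimension — the standard MFA treatment of continuous coordinate groups; no
unit-variance scaling of individual columns is applied, since x and y of
one sheet share a unit.  Eigenvalues are the squared singular values of the
weighted concatenated matrix, with no $n-1$ normalization (percent variance
is scale-free either way).  A consequence worth knowing: duplicating the
whole panel doubles every eigenvalue and scales scores by $\sqrt2$ while
leaving the percent-variance profile and the configuration shape unchanged.
Each dimension's sign is fixed so its largest-magnitude score is positive.

A bridge identity ties the two routes together and is asserted at $10^{-8}$:
Euclidean distances between full-dimensional MFA scores equal
`concatenated_distances(center_per_rater = TRUE, weight_per_rater = TRUE)`.

**Bootstrap ellipses.**  Several resampling schemes exist; the package uses
the simplest defensible one: resample *raters* with replacement ($B = 500$,
level 0.95 by default), refit the MFA, align each replicate's 2-D
configuration to the reference by orthogonal Procrustes (rotation +
reflection + translation, no scaling — scale is informative after the
$1/\sigma_1$ weighting), and summarize each product's bootstrap cloud by a
bivariate-normal ellipse at the $\chi^2_2$ quantile.  The normal
approximation is smooth at moderate $B$, unlike convex-hull peeling.
Degenerate resamples (all copies of a zero-spread rater) are skipped with a
warning and counted.

## QDA statistics

Line-scale scores (default 15 cm, anchors 0–100) are analyzed on their
recorded scale.  `panel_average()` averages across raters per serving and
attribute; `attribute_anova()` fits one- or two-way least-squares models per
attribute and reports factor F-tests with the conventional significance
codes (* 0.05, ** 0.01, *** 0.001).  `pairwise_ttests()` uses the pooled
one-way residual SD — consistent with the F-test and with CI bars drawn
from a common error term ($F = t^2$ for two groups is asserted in the
tests); Welch is available behind a flag because the reference analyses do
not state which variant was used, and both per-group-mean and per-difference
intervals are emitted for the same reason.

`subject_effects_anova()` analyses panelist-level records with fixed rater
effects: the F-test compares `score ~ rater + group` against
`score ~ rater`.  Its reason to exist is asserted directly in the tests:
adding a constant to one rater's scores leaves this F unchanged but changes
the naive pooled ANOVA.  Random subject effects are delegated to `lme4`
when installed (optional path, not part of the core surface).  By default
attribute-wise p-values are reported raw — many attributes are tested, so
they should be read exploratively — with Holm available.

`pvalue_ecdf()` supports the uniformity diagnostic: with no true group
differences, attribute p-values are uniform and their ECDF hugs the
diagonal; the Kolmogorov–Smirnov distance $\sup_p |\hat F(p) - p|$
summarizes the departure, and pooling across studies is supported.

## The synthetic world

`simulate_napping()` states the world the tests operate in: $n = 10$
products in four latent clusters of sizes 2, 6, 1, 1 (two replicate
servings of five breed/feeding groups — the design of the reference
minced-thigh panel), cluster centers about 20 cm apart, within-cluster
spread 1 cm, $m = 12$ raters, each observing the latent configuration
through an independent similarity transform (rotation uniform on
$[0, 2\pi)$, reflection w.p. 0.5, translation uniform in $\pm 10$ cm,
log-normal scale with log-SD 0 by default) plus isotropic 1 cm placement
noise.  Descriptors come from per-cluster vocabularies with emission
probability 0.8, otherwise from a noise pool shared across clusters, so
profiles are discriminative but not trivially separable.  Where the
reference study states a quantity (10 products, 12 panelists, 4 clusters
with these sizes, 16 QDA attributes, the 15 cm scale, 5 groups × 2
servings) the defaults are that quantity; the remaining magnitudes (1 cm
noise against 20 cm separation, unit rater-offset and residual SDs
mid-scale) were chosen once as values a sensory scientist would call a
competent trained panel, and are not tuned.

Randomness flows from one seed with a deterministic sub-stream per rater,
so enlarging the panel never perturbs earlier raters' data.  Per-rater
scale is part of the model but defaults to log-SD 0, keeping the noise-free
distance-recovery tests exact; scale is switched on only in robustness
tests.

What a green test does **not** establish: real panels disagree more
interestingly than isotropic Gaussian noise (rater-specific distortions,
attention to different attributes, partial sheets), descriptors are not
multinomial draws, and QDA scores are not homoscedastic normals.  The
generator validates the machinery, not the sensory method.

## Numerical choices and degenerate inputs

* Distance matrices are validated for symmetry ($10^{-8}$ relative), zero
  diagonal, nonnegativity; missing cells are `NA`, never 0, and pairs
  observed by no rater are a hard error by default since clustering needs a
  complete matrix.
* Averaging raw distances is the default; averaging squared distances
  (then square-rooting) is a flag, as is per-rater RMS normalization —
  neither is implied by the method itself, so both are off by default.
* `concatenated_distances()` defaults to centered, unweighted blocks:
  centering buys translation invariance, while $1/\sigma_1$ weighting is an
  MFA convention, not part of the raw-distance route.
* A rater placing all products at one point has $\sigma_1 = 0$ and is
  reported by name; sheets with fewer than two placed products are
  rejected.
* Exact-test ties use the $1+10^{-7}$ relative tolerance above; log-space
  factorials keep $N$ up to the thousands stable.
* UPGMA tie-breaks, cluster-id numbering (by first product appearance) and
  the MFA sign convention exist purely for cross-platform determinism.

## Limitations

Only the worked-example contingency table is reproducible from the
reference study (its raw panel data are unpublished); all other claims are
covered by property-based tests against independent oracles and seeded
simulations.  The clustering offers UPGMA only; DISTATIS-style individual
difference scaling, non-Euclidean sheet geometries, hierarchical MFA and
panel-performance indices are out of scope.  The bootstrap ellipse is one
of several published variants; with few raters ($m \lesssim 6$) rater
resampling understates uncertainty and the ellipses should be read
qualitatively.
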