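---
title: "Detecting spatially co-expressed ligand-receptor pairs with bivariate Moran statistics"
author: "spaMoran"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatially co-expressed ligand-receptor pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaMoran)
```

# The problem

Cell-cell communication is usually inferred from transcriptomics by asking
which ligand-receptor (LR) pairs from a curated database are co-expressed.
Single-cell methods can only pair cell *types*; they cannot verify that the
putative sender and receiver are physically near each other, which inflates
false positives. Sequencing-based spatial transcriptomics (ST) measures
expression at spots with known coordinates, so the question becomes directly
testable: *is the ligand expressed where (or next to where) its receptor is
expressed?*

`spaMoran` answers this with a bivariate extension of Moran's I. For
normalized, log-transformed ligand expression $x$ and receptor expression $y$
over $n$ spots and a spatial weight matrix $w$,

$$
R \;=\; \frac{\sum_i \sum_j w_{ij}\,(x_i - \bar x)(y_j - \bar y)}
       {\sqrt{\sum_i (x_i-\bar x)^2}\,\sqrt{\sum_i (y_i-\bar y)^2}} .
$$

$R$ is a spatially lagged cross-correlation: positive when high ligand sits
near high receptor, zero in expectation when the two profiles are spatially
unrelated, and invariant to location and positive scale changes of either
input. Multi-subunit complexes enter as the per-spot arithmetic mean of their
subunits' expression (a geometric-mean mode is available for stringent
analyses, where one absent subunit zeroes the complex).

# The spatial weight matrix

All statistics are localized by an $n \times n$ proximity matrix, built in
one of two ways:

* **RBF kernel** (`rbfWeights`): $w^{(0)}_{ij} = \exp\{-d_{ij}^2/(2l^2)\}$
  with Euclidean spot distance $d_{ij}$; entries with kernel value below a
  `cutoff` are zeroed so that secreted signalling is restricted to a
  physically plausible radius ($d \le l\sqrt{-2\ln(\text{cutoff})}$). The
  length scale is expressed in the platform's coordinate units; for an
  ST-era array with unit spacing between spots (200 um), `l = 1.2` and
  `cutoff = 0.2` restrict support to roughly a two-spot radius, and a
  Visium-like coordinate scale would use proportionally larger `l`.
* **K nearest neighbours** (`knnWeights`): binary adjacency to the `k = 6`
  closest spots, the natural choice for juxtacrine (contact / ECM)
  signalling on hexagonal arrays. Ties at the k-th distance are broken by
  spot index so results are reproducible; the adjacency is directed by
  default, with an optional symmetrization.

After the cutoff (and optional zeroing of the diagonal for
single-cell-resolution platforms, which removes the self-pairing term), the
matrix is rescaled so that $\sum_{ij} w_{ij} = n$. The order matters: the
normalizing mass must be that of the matrix actually used, otherwise the
moments below are wrong. Both builders enforce this invariant, and the class
validity checks it.

# Hypothesis testing

Two nulls are offered:

* **Permutation**: the receptor's spot labels are permuted (equivalent to
  shuffling the weight matrix); the one-sided p-value is the fraction of
  permuted $R$ at least as large as the observed one, floored at
  $1/(n_{\text{perm}}+1)$ so downstream $-\log$ and FDR transforms stay
  finite. One seeded permutation set is shared across pairs.
* **Analytic z-score**: under the permutation null, $E[R] = 0$ exactly and
  the variance has the closed form
  $$
  \mathrm{Var}(R) = \frac{n^2\sum_{ij} w_{ij}^2
      - n\left(\sum_i r_i^2 + \sum_j c_j^2\right) + S_0^2}
      {n^2(n-1)^2},
  $$
  with $r_i$, $c_j$ the row and column sums and $S_0$ the total mass. For
  symmetric weights this reduces to the familiar product-of-margins form;
  the general expression also covers directed KNN weights. The derivation
  uses only the exchangeable permutation moments, so it can be (and is)
  checked against an exhaustive enumeration of all $n!$ permutations at
  small $n$: the test suite requires agreement to $10^{-10}$ at $n = 7$ and
  within Monte-Carlo error at $n = 200$. $z = R/\sqrt{\mathrm{Var}(R)}$ with
  the upper-tail normal p-value replaces the permutation loop and is what
  makes the method scale to very large spot counts.

Testing is one-sided throughout: negative spatial association is visible in
the sign of $R$ but is never selected. Across database pairs, p-values are
Benjamini-Hochberg adjusted and pairs with FDR below the threshold (default
0.1) are selected. Pairs whose composite ligand or receptor is constant are
reported as untested rather than given a fake p-value.

An optional fine-tuned statistic $R' = w_l I_l + w_r I_r + R$ adds the
univariate auto-correlations of ligand and receptor; both weights default to
0 (plain $R$), matching the recommended setting for experimental data, while
a small $w_l$ (for example 0.17) can help on simulated data where truly
interacting ligands are themselves spatially structured.

# Local statistics

For each selected pair the per-spot statistic on gene-wise standardized
(population sd, then clipped to $\pm 10$) inputs $x'$, $y'$ is

$$
R_i = \underbrace{x'_i \textstyle\sum_j w_{ij} y'_j}_{\text{sender}}
    + \underbrace{y'_i \textstyle\sum_j w_{ij} x'_j}_{\text{receiver}},
$$

whose two halves attribute signal to ligand-at-spot versus
receptor-at-spot. Standardization makes the local values comparable across
pairs and samples at the cost of discarding absolute expression level; it
can be switched off (`standardized = FALSE`), in which case centered,
unscaled values are used and only the permutation test is offered. The exact
permutation variance of $R_i$ is

$$
\mathrm{Var}(R_i) = \sigma_1^2\sigma_2^2\left[
  \frac{2\,(n\sum_j w_{ij}^2 - r_i^2)}{n-1}
  + \frac{2\,(n\,w_{ii} - r_i)^2}{(n-1)^2}\right],
$$

which tends to $2\sigma_1^2\sigma_2^2(\sum_j w_{ij}^2 + w_{ii}^2)$ for large
$n$ and row-normalized weights. We implement the exact form because the
exhaustive-permutation oracle is the arbiter in our tests; the practical
difference from the large-$n$ form is $O(1/n)$. In single-cell mode
($w_{ii}=0$) the diagonal contribution drops to an $O(1/n^2)$ row-sum
correction.

A **quadrant filter** then suppresses "low-low" spots: if both the centered
ligand and the centered receptor at spot $i$ are $\le 0$, $p_i$ is forced to
1, so neighbourhoods that merely share *absence* of signal can never be
called interaction hits. Hits are spots with $p$ below 0.1 (raw, one-sided;
no per-spot FDR is applied, matching common practice of thresholding local
indicators of spatial association directly).

# Downstream analyses

* **Communication patterns** (`clusterPatterns`): each selected pair's
  binary hit vector is smoothed with a row-stochastic RBF kernel over the
  coordinates and the smoothed profiles are clustered with seeded k-means.
  This is a deliberate, self-contained stand-in for Gaussian-process
  "automatic expression histology" clustering: it preserves the property
  that matters (pairs hitting the same tissue region cluster together, and
  pattern intensities are spatially smooth) without the GP mixture
  machinery. Pairs with fewer than `minHits = 10` hit spots are excluded as
  uninformative.
* **Pathway enrichment** (`pathwayEnrichment`): one-sided Fisher's exact
  test per pathway on the (selected vs not) x (in pathway vs not) table over
  database pairs; pathways with fewer than two selected pairs are flagged.
* **Chord edge weights** (`chordCellType`, `chordLR`): with per-spot
  cell-type weights (e.g. from deconvolution, supplied as input), the edge
  mass sent from type $A$ to type $B$ is
  $n_{AB} = \sum_{ij} w_{ij}\,R_{i,\text{sender}} A_i\,R_{j,\text{receiver}} B_j$,
  bilinear in the type weights; the per-pair variant scores each
  interaction on a given type combination.
* **Cell-type regression** (`celltypeRegression`): ordinary least squares
  from the spots x pairs matrix of local p-values to the cell-type weights,
  summarized by the Pearson correlation between predicted and observed
  weights — a global check that local hits track tissue composition.
* **Differential interaction** (`differentialTest`): per pair, the global
  z-scores across samples (undetected pairs entering as 0) are fit by
  maximum likelihood under a Gaussian linear model with and without the
  condition term; $2\Delta\ell$ is referred to $\chi^2_1$, BH-adjusted, and
  significant pairs are labelled condition-specific using the 30%/70%
  quantiles of the z-difference. The same code path accepts a continuous
  covariate (time, pseudotime). **Small-sample caveat**: with very few
  samples per condition (e.g. 3 + 3) the $\chi^2$ reference is
  anticonservative — the exact null of the Gaussian LRT maps to an
  F-distribution with few denominator degrees of freedom — so raw
  differential p-values at such designs should be read as a ranking; the
  calibration property is recovered at moderate sample counts (the suite
  checks uniformity at 10 + 10).

# The synthetic-data generator

`simulateNull` / `simulateInteracting` generate seeded, fully reproducible
datasets on a unit lattice (or uniform random layout). Latent log-intensity
fields are sums of standardized components with configurable variance
fractions:

* **interaction** — spatially weighted neighbour receptor expression,
  $W\,y$, with $W$ the package's own RBF weights (`l = 1.2`,
  `cutoff = 0.2`);
* **environment** — a Gaussian process with RBF covariance (length scale
  1.5 lattice units, i.e. spatial domains spanning a few spots, like small
  tissue regions);
* **intrinsic** — the paired receptor profile itself (off by default);
* **noise** — white Gaussian.

Counts are then drawn as Poisson with log-normal intensity (log-sd 0.8,
mean 1 count per gene per spot), emulating shallow sequencing; ligands whose
realized correlation with their receptor is negative have their sign
flipped, so "interacting" always means positively associated. The default
split of the non-interaction variance is 5% environment / 95% noise. That
choice encodes a real property of sequencing-based ST: per-gene variance is
dominated by sampling noise, and variance-component decompositions of such
data attribute only a small share to smooth spatial structure. It also marks
the boundary of the method's calibration: a bivariate Moran test referred to
permutation moments is anticonservative when *both* profiles are strongly
autocorrelated (the classic correlated-backgrounds problem), so the
calibrated-null behaviour verified by the test suite is a statement about
this noise-dominated regime, not about arbitrarily smooth data. Users
analysing very smooth fields (large environmental share, long length
scales) should prefer the permutation mode and treat borderline analytic
p-values with caution.

What the generator does *not* emulate: segmentation artefacts, spot-level
cell-type mixtures, zero inflation beyond Poisson sampling, and platform
chemistry effects. Passing tests on synthetic data therefore demonstrate
statistical correctness (calibration, power ordering, oracle agreement),
not end-to-end biological validity on any particular tissue.

`fitVarianceComponents` closes the loop: it fits, by maximum likelihood
(L-BFGS-B over log-variances, three seeded restarts, diagonal jitter on
Cholesky failure), a zero-mean multivariate normal whose covariance is the
weighted sum of a linear kernel on receptor subunits (intrinsic), an RBF
kernel on coordinates (environment), the covariance of the spatially
weighted receptor profile (interaction), and the identity (noise), each
trace-normalized so fitted weights read directly as variance fractions.
With one receptor subunit the intrinsic and interaction kernels are both
rank-one and correlated, so single-pair fractions are noisy; recovery
checks therefore average a few pairs and use generous tolerances.

# Numerical and design choices

* Population (divide-by-$n$) standard deviations everywhere in the local
  machinery; the exhaustive permutation oracle fixes this convention.
* Permutation p-values floored at $1/(n_{\text{perm}}+1)$; one shared
  permutation set across pairs (a per-pair set costs
  $n_{\text{perm}}\times$ more and changes nothing under the null).
* KNN ties broken by spot index; duplicated coordinates are legal.
* Weight matrices are backed densely below 5000 spots and sparsely above;
  the arithmetic contract is identical.
* Degenerate inputs (constant ligand or receptor) are reported as untested
  rather than erroring out of a whole screen.
* Problem sizes used by the test suite and acceptance script — a 300-spot
  lattice, 250-500 pairs, 1000 permutations, $2\times 10^5$ Monte-Carlo
  draws — were chosen as the smallest sizes at which the statistical
  claims (calibration, concordance, monotone power) are stable.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulateInteracting(simConfig(nSpots = 300, nPairs = 100,
                                     interactionFraction = 0.5, seed = 42))
w <- rbfWeights(sim$coords, l = 1.2, cutoff = 0.2)
g <- runGlobal(sim$sample, sim$db, w, method = "zscore", fdrThreshold = 0.1)
g

loc <- runLocal(sim$sample, g, sim$db, w)
pat <- clusterPatterns(hitsMatrix(loc), sim$coords, K = 3, seed = 1)
en  <- pathwayEnrichment(selectedPairs(g), sim$db)
head(en)
```

# Known limitations

* The analytic null assumes exchangeability; strongly autocorrelated
  marginals inflate the z-test (see the generator section). The permutation
  mode shares the same null, so the caveat applies to both.
* Pair-by-pair testing ignores pleiotropy (several ligands sharing one
  receptor) and the compositional coupling induced by library-size
  normalization, which matters for small gene panels.
* The LRT for differential interaction is anticonservative at very small
  sample counts (see above).
* Pattern clustering is a kernel-smoothing approximation of GP expression
  histology; patterns are labels over *selected* pairs only.
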