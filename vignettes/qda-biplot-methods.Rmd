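---
title: "Methods: visualising quadratic discriminant analysis"
author: "qdabiplot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visualising quadratic discriminant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(qdabiplot)
```

## The problem

Canonical variate analysis (CVA) gives the classical two-dimensional
picture of group separation: because all groups are assumed to share one
within-group covariance matrix, a single linear transformation maps every
sample into one canonical space, where classification is to the nearest
class mean (plus a log-prior term) and the display is an honest picture of
the discriminant rule.

That single shared transformation is exactly what quadratic discriminant
analysis (QDA) gives up. When groups have different covariance structures —
the typical situation when diseased patients are more variable than healthy
ones, or when presence/absence panels differ in co-occurrence between
patient groups — each class \(j\) gets its own covariance \(S_j\), the
decision surfaces become quadrics, and there is no one linear map to a
common display space. `qdabiplot` implements a display that restores the
picture: transform each sample through every class's own quadratic score,
and let those J scores *be* the new variables.

## The model and the display construction

With class means \(\bar{x}_j\) and unbiased class covariances \(S_j\)
(divisor \(n_j - 1\)), the per-class quadratic score is

\[
\phi_j^2(x) = (x - \bar{x}_j)' S_j^{-1} (x - \bar{x}_j) + \log|S_j|,
\]

and a sample is classified to
\(\arg\max_j \{\log \pi_j - \tfrac12 \phi_j^2(x)\}\). All quadratic forms
are evaluated through the Cholesky factor of \(S_j\); no explicit inverse
is ever formed, and a failed factorization is reported as the
positive-definiteness error (typically \(p > n_j - 1\)).

The display is built in three steps.

1. **Score matrix.** Evaluate \(\phi_j^2(x_i)\) for every sample and class
   and standardize each of the J columns to mean 0, SD 1 (sample SD,
   divisor \(n - 1\)). Standardization matters because one concentrated
   group otherwise collapses against the decision boundary while a diffuse
   group dominates the scale.
2. **PCA.** The first two principal components of the standardized
   \(n \times J\) score matrix give the sample coordinates. The columns
   are mean-zero by construction, so the PCA is computed without
   re-centring (the stored centre offset is identically zero), and since
   every column has unit SD the covariance and correlation forms coincide.
   Component signs are fixed by making each loading column's
   largest-magnitude entry positive, so plots reproduce across platforms.
   For \(J = 2\) the two components represent the score matrix exactly.
3. **Regions by back-projection.** Any display point \(z\) maps back to
   approximate raw scores
   \(\hat\phi_j^2(z) = s_j\,(V_r z)_j + \bar\phi_j\), where \(V_r\) holds
   the retained loadings — the standard PCA inverse map, which is the
   unique linear right-inverse on the retained subspace and exact when
   \(r = J\). Applying the discriminant rule to \(\hat\phi^2(z)\) over a
   regular lattice (default \(400 \times 400\) with a 10 % window margin)
   yields the coloured classification regions.

For exactly two groups the package also draws the direct scatter of
\(\phi_2^2\) against \(\phi_1^2\) (`twoGroupPlot()`). Unscaled, the equal-
prior boundary is literally the line \(y = x\); the default scales each
coordinate by its SD for readability, while region labels are always
computed from the raw scores so the rule itself never changes.

## Variables as calibrated axes

Each original variable is fitted into the display by the regression method:
the direction is \(b_k = (Z'Z)^{-1} Z' x_k\) for centred column \(x_k\), so
orthogonal projection of a score onto the axis reads off the least-squares
fitted value \(z'b_k + \bar{x}_k\). Tick markers are placed at round values
chosen by a 1-2-5 rule over the observed range (just 0 and 1 for binary
variables). `translateAxes()` then shifts each axis perpendicular to its
direction until it clears the convex hull of the sample cloud, on whichever
side is nearer — a pure readability device: because the shift is orthogonal
to the direction, read-off values are provably unchanged. Every rendered
plot keeps a 1:1 aspect ratio; without it, orthogonal projection on paper
would not correspond to orthogonal projection in the display geometry.

## The benchmark generator

`threeGroupSpec()` encodes the bundled simulation benchmark: three
four-variate normal groups of 50 samples with means \((1,1,1,1)\),
\((-1,2,3,4)\), \((1,1,5,5)\) and covariances \(I_4\), \(2 I_4\), and unit
variance with equicorrelation 0.7 — one tight spherical group, one inflated
spherical group, one strongly correlated group, so the three covariance
structures genuinely differ. `dichotomizeAtMedian()` converts the same draw
to 0/1 indicators (pooled median over all 150 samples per variable,
midpoint convention at even counts, the value 1 assigned at or above the
median), emulating presence/absence panels; `pathogenPanel()` draws
independent Bernoulli panels with class-specific presence probabilities at
any dimension. Identical binary response patterns share a display point, so
glyphs are collapsed by majority vote (`collapsePatterns()`), ties to the
lowest class index.

What the generator does *not* emulate: correlated pathogen co-occurrence
(panels are independent Bernoulli given the class), measurement error,
missingness, or covariate effects. Passing tests on these fixtures
therefore demonstrate the correctness of the algebra and the display
contract — not that QDA is an appropriate model for any particular real
panel.

```{r example, eval = FALSE}
d <- simulateNormal(threeGroupSpec())
m <- buildPhiMatrix(d, fitQuadratic(d, priors = "proportional"))
lay <- buildRegionGrid(qdaScores(d, m), m)
lay@axes <- translateAxes(regressionAxes(lay, d), lay)
plot(lay)
```

## Numerical and design choices

* **Covariance divisor.** Unbiased \(n_j - 1\) throughout (`stats::cov`),
  the standard QDA convention; it also makes the large-sample consistency
  checks clean.
* **Eigenproblem.** The canonical directions solve \(BM = WM\Lambda\)
  subject to \(M'WM = I\). This is computed as a symmetric problem —
  Cholesky-whiten by \(W = R'R\), symmetric eigendecomposition of
  \(R^{-T} B R^{-1}\), map back by \(R^{-1}\) — never by forming
  \(W^{-1}B\), which would destroy symmetry and stability. At most
  \(J - 1\) eigenvalues are meaningfully nonzero; asking for more display
  dimensions warns rather than fails.
* **LDA scale.** Nearest-mean classification in canonical space carries the
  factor \(n - J\) on the squared distance, converting the W-normalised
  metric to the pooled-covariance Mahalanobis scale so that the log-prior
  term enters with its proper weight.
* **Ties.** Every argmax breaks ties toward the lowest class index,
  deterministically — a sample exactly on the two-group identity line is
  class 1.
* **Ridge for binary panels.** A binary variable that is constant within
  one class (it happens: in the bundled dichotomized benchmark every
  group-1 value of V4 falls below the pooled median) makes that class
  covariance exactly singular and QDA undefined. `fitQuadratic(...,
  ridge = eps)` adds \(\epsilon I\); it is off by default and we recommend
  0.05 (a fifth of the maximal Bernoulli variance 0.25) when a panel
  triggers the singularity error. Continuous data should not need it.
* **Degenerate displays.** Two classes give a rank-1 canonical space; the
  CVA layout warns and plots the single canonical variate horizontally. A
  zero-variance score column (all samples equidistant from one class)
  aborts with an explanation rather than dividing by zero.
* **Grid defaults.** \(400 \times 400\) lattice, 10 % margin — fine enough
  that the rendered two-group boundary sits within one lattice step of the
  exact identity line, cheap enough to rebuild interactively. Refining the
  lattice never relabels an existing lattice point, because each point is
  classified independently.
* **Priors.** Default proportional to class size, the natural choice for
  observational case/control panels; `"equal"` or an explicit vector are
  accepted everywhere priors enter.

The test-suite problem sizes (n = 150–200 fixtures for the display
contracts, \(n_j = 10{,}000\) draws for the parameter-recovery and
consistency checks, 400-point lattices for boundary measurements) were
chosen so the whole suite runs in seconds while keeping Monte-Carlo
tolerances, derived from standard-error bounds, meaningful.

## Known limitations

* The display is exact for two groups but a rank-2 approximation for
  \(J \ge 3\): back-projected scores — and hence the drawn regions and the
  per-group region accuracies — can deviate from full-space QDA, and the
  quality of the approximation varies with the draw. The display is a
  visualisation aid, not a substitute for classifying with `qdaClassify()`.
* Three-dimensional displays, cross-validated error estimation, automatic
  variable selection and regularized discriminant analysis beyond the
  single ridge constant are out of scope.
* With binary data the quadratic model is used descriptively; the normal
  likelihood it derives from is at best an approximation there, and the
  package makes no distributional claim for that case beyond what the
  benchmark comparison shows qualitatively.
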