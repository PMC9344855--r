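---
title: "Quantifying marker co-expression with quadratic mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker co-expression with quadratic mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmi)
```

## The model

For subject $j$ with $n_j$ segmented cells and $p$ markers, the intensities
$X_{kij}$ ($k = 1,\dots,p$) are modelled as draws from a subject-specific
joint density $f_{1\dots p,j}$ on $[0,1]^p$ with marginals $f_{kj}$.
Co-expression is dependence among the markers, measured by the Euclidean
quadratic mutual information

$$\mathrm{EQMI} = V_J - 2V_C + V_M
  = \int \bigl(f_{1\dots p} - \textstyle\prod_k f_k\bigr)^2,$$

with $V_J = \int f_{1\dots p}^2$, $V_C = \int f_{1\dots p}\prod_k f_k$ and
$V_M = \int \prod_k f_k^2$. EQMI is zero iff the markers are independent and,
unlike the Pearson correlation, registers arbitrary (non-linear,
non-monotone) dependence; unlike Shannon mutual information it admits the
closed-form plug-in estimator below, which is what makes it usable beyond
two or three markers. Because EQMI has no common upper bound across
subjects, the package reports the standardized

$$\mathrm{EQMI}^* = \frac{V_J - 2V_C + V_M}{V_J + V_M} \in [0,1],$$

which is comparable across subjects ($V_C \ge 0$ gives the upper bound).
The Cauchy–Schwarz variant $\mathrm{CSQMI} = \log(V_J V_M / V_C^2)$ is
reported alongside but not used for testing.

## The estimator

Substituting Gaussian kernel density estimates with per-marker bandwidths
$h_k$ into the three integrals and using the convolution identity
$\int G_h(x-a)\,G_h(x-b)\,dx = G_{\sqrt2 h}(a-b)$ gives exact closed forms
in the per-marker kernel matrices
$K_k(i,s) = G_{\sqrt2 h_k}(X_{kij} - X_{ksj})$:

$$\hat V_J = \frac1{n^2}\sum_{i,s}\prod_k K_k(i,s),\qquad
  \hat V_C = \frac1n\sum_i \prod_k \bar K_k(i),\qquad
  \hat V_M = \prod_k \frac1{n^2}\sum_{i,s} K_k(i,s),$$

with $\bar K_k(i)$ the $i$-th row mean. Only one $n\times n$ matrix is held
at a time ($O(n^2p)$ time, $O(n^2)$ memory); no $p$-dimensional grid is
ever formed. The $\sqrt2$ widening is not a convention but a theorem — it
is what makes $\hat V_J$ *equal* $\int \hat f_{1\dots p}^2$ exactly — and
two independent oracles in the test suite pin it down: a naive triple-loop
evaluation of the sums (agreement to $10^{-12}$ relative) and a
two-dimensional gridded-KDE quadrature of the integrals themselves
(`vterms_quadrature()`, agreement to $10^{-4}$). Because
$\hat V_J - 2\hat V_C + \hat V_M = \int(\hat f_{1\dots p} -
\prod_k\hat f_k)^2 \ge 0$ algebraically, the estimated EQMI* lands in
$[0,1]$ up to floating-point error; values are clipped only within a
$10^{-10}$ numerical slack and anything beyond that raises an error rather
than being silently truncated.

The derivation allows $h_k \ne h_{k'}$: each marker keeps its own
bandwidth, which matters because marker intensity distributions differ
wildly in scale and skewness. With all $h_k$ equal the formulas reduce to
the single-bandwidth case through the same code path.

## Bandwidth selection

Bandwidths are selected per subject from that subject's own cells — each
subject has its own densities, and per-subject selection keeps EQMI*
comparable across subjects with very different cell counts. Two diagonal
(per-marker, univariate) selectors are provided:

* `bw_plugin()` (default): the two-stage direct plug-in selector
  (`stats::bw.SJ(method = "dpi")`), falling back to Silverman's rule with a
  warning if the plug-in equations fail, and switching to Silverman outright
  for $p > 6$ markers where per-marker plug-in cost adds up.
* `bw_silverman()`: $h_k = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,
  n^{-1/5}$.

Bandwidths are floored at $10^{-6}$ so near-duplicate intensities cannot
degenerate the kernels. A fixed `bw_fixed()` set can be forced globally for
sensitivity analysis. Intensities are first mapped to $[0,1]$; the default
`global_minmax` pools the per-marker min/max over *all* subjects because
EQMI* values are compared across subjects, which argues for one shared
scale. Per-subject min–max and a winsorized variant (`quantile_cap_minmax`,
cap 0.99, robust to hot pixels) are selectable. Multiple images of one
subject are pooled into a single cell set; `image_id` is kept for filtering
only. Rows with missing marker values are dropped, never imputed. Subjects
that cannot support estimation (fewer than 2 cells, a constant marker) are
excluded with a warning instead of failing the run.

## Association testing

With $E_j = \widehat{\mathrm{EQMI}}^*_j$ and optional covariates $C_j$:

* continuous $Y$: OLS $Y = C\beta + E\gamma + \epsilon$, Wald test of
  $\gamma = 0$ (a joint $\chi^2$ Wald when polynomial terms
  $E^2, E^3,\dots$ are requested via `poly_degree`);
* binary $Y$: logistic regression, Wald test; complete separation is
  flagged and the p-value withheld rather than reported as spuriously tiny;
* right-censored $Y$: Cox proportional hazards
  $\lambda_j(t) = \lambda_0(t)\exp(C_j^T\beta + E_j\gamma)$ with a 1-df
  likelihood-ratio test for $E$ and the hazard ratio $e^{\hat\gamma}$
  reported. Ties are handled by the Efron approximation by default
  (Breslow selectable; the brute-force partial-likelihood oracle in the
  tests uses Breslow on tie-free data so both definitions coincide).

`combination_scan()` evaluates every marker subset of size $\ge 2$
($2^p - p - 1$ subsets) and corrects multiplicity *within each subset
size*: pairs compete with pairs, triplets with triplets, so
`bonferroni_alpha` is $\alpha$ divided by the number of same-size subsets.
The scan refuses $p > 10$; beyond that a pre-selected functional-marker
panel is the sensible unit of analysis. The test level defaults to
$\alpha = 0.05$ throughout, and covariate adjustment is always explicit,
never implicit.

## Comparator methods

The thresholding pipeline reproduces the traditional analysis: per-marker
cutoffs at a pooled quantile (0.5, 0.95, 0.99 for the named median /
threshold-1 / threshold-2 comparators; type-7 linear-interpolation
quantiles, stated because quantile dialects differ), strict positivity
$X > t_k$ (ties are negative), per-subject pairwise proportions
(both-positive, first-only, second-only for each pair; the full
$2^p - 1$-pattern vector is opt-in), Ward/Euclidean hierarchical clustering
cut at $M = 2$ (linkage configurable; labels renumbered by first appearance
for reproducibility), and the same outcome tests applied to the cluster
indicator. `abs_pearson_coexpression()` supplies the two-marker $|r|$
comparator.

## The simulation framework

The generators emulate the regime the method targets: two latent groups of
subjects, one with high marker co-expression and one with little or none,
and a subject-level outcome $Y_j = I_j\beta + \epsilon_j$,
$\epsilon_j \sim N(0, \sigma^2)$ carrying the group signal. Scenarios:

* `copula2`: bivariate Gaussian copula; high group draws a per-subject
  latent correlation $\rho_j \sim U(0.75, 0.9)$, low group
  $U(0, 0.15)$; marginals Beta(1.5, 170) and Beta(1.6, 35) — the highly
  skewed, near-zero-mode shapes typical of functional-marker intensities.
* `squared`: $X_1 \sim U(0, 0.1)$,
  $X_2 = (X_1 - 0.05)^2 + e$, $e \sim U(0, 0.0005)$ — deterministic
  dependence with population correlation exactly zero.
* `circular`: $X_2 = 0.05 + s\sqrt{0.05^2 - (X_1-0.05)^2} + e$ with
  $s \sim U(-1, 1)$ read literally ("a random number between −1 and 1"); a
  Rademacher $s = \pm1$ option puts the cells on the circle itself, since
  that reading is also plausible.
* `copula3_caseA/B/C`: trivariate copula, active correlations
  $U(0.4, 0.6)$ vs $U(0.2, 0.4)$, with case B zeroing $\rho_{13}$ and case
  C zeroing $\rho_{13}, \rho_{23}$ in both groups; non-positive-definite
  draws are redrawn.

Every generator is a deterministic function of its seed. The power engine
generates intensities once per dataset repeat, computes each method's
per-subject statistic once, then sweeps the effect-size grid with repeated
outcome draws; all methods see identical outcome vectors, so power
*differences* are estimated with far less Monte-Carlo noise than the powers
themselves. A thresholding repeat whose clustering degenerates counts its
replicates as non-rejections — a method failure is a failure, not missing
data.

Where the outcome model's noise scale is not dictated by the design we set
$\sigma = 1$ with effect sizes $\beta \in \{0, 0.5, 1, 1.5, 2\}$, i.e.
group separations of 0–2 noise SDs, spanning no power to near-saturation
for an informative statistic at $N = 40$. The package's reference study
size is $N = 40$ subjects, 1000 cells per subject, 20 outcome draws × 5
dataset repeats (100 replicates per power estimate, Monte-Carlo SE
$\le 0.05$); the full-budget 100 × 20 design is a configuration change.

## What the simulations do and do not show

The generators produce continuous, exchangeable cells with exactly the
stated dependence structures. Real multiplex images add features the
simulations deliberately omit: spatial autocorrelation among neighbouring
cells (cells are *not* i.i.d. within a tissue), segmentation spillover that
induces artifactual positive dependence between markers of adjacent cells,
batch and staining effects that shift whole marginals, zero-inflation at
the detection floor, and cell-type mixtures. Passing the simulation suite
therefore demonstrates correctness of the estimator and the comparative
behaviour of the methods under clean dependence — not robustness to those
artefacts. In particular EQMI*, like any marginal-dependence measure,
cannot distinguish *which kind* of dependence two subjects have: a linear
and a circular pattern of equal strength can give similar EQMI*.

Two empirical findings from the test suite deserve flagging. First, with
1000 cells per subject the quantile-threshold comparators are not as weak
as one might expect in the circular scenario: the group difference in
marginal tail proportions, while small (~0.03), is several binomial
standard errors at $n = 1000$, so threshold-based clustering separates the
groups and its power saturates together with EQMI*'s. The advantage of
EQMI* over thresholding in that scenario shows at scarcer cell counts
(the suite checks the ordering at 100 cells per subject), which is also the
regime of small regions of interest in practice. Second, $|r|$ is not
perfectly uninformative under the parabola: its sampling spread is larger
in the dependent group ($\approx 1.25/\sqrt n$ vs $1/\sqrt n$), a
second-order group signal that a strong outcome effect can partially
detect; its power nevertheless stays far below EQMI*'s.

## Numerical choices

* Kernel matrices use the exact $\sqrt2 h_k$ convolution bandwidth;
  diagonal entries equal $1/(2h_k\sqrt\pi)$.
* The quadrature cross-check integrates on a 501-point-per-axis trapezoid
  grid extended $6\max(h)$ beyond $[0,1]$ so truncated kernel tails sit
  below the $10^{-4}$ comparison tolerance.
* $V_J + V_M = 0$ (possible only for empty input) and $V_C = 0$ (CSQMI
  infinite) are explicit degenerate conditions, not NaNs.
* Hierarchical clustering errors out when fewer than $M$ distinct profile
  vectors exist instead of returning arbitrary splits.
* Seeds: all generators route through a single integer seed; repeat-level
  seeds are fixed offsets of it, and RNG state is restored afterwards
  (`withr::with_seed`).

## Limitations

Beyond the data features above: the combination scan is exponential in $p$
and Bonferroni within sizes is conservative when subsets overlap (they
share markers, hence are positively dependent); multinomial outcomes are
not supported (binary logistic only); spatial locations of cells are
ignored; and pixel-level analysis is out of scope — the package consumes
segmented cell tables only.
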