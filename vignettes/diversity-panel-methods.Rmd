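---
title: "Methods: RCBD variance components, genetic parameters, and multivariate structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RCBD variance components, genetic parameters, and multivariate structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgpanel)
```

## The model

A diversity panel of G genotypes is grown once per block in r complete
blocks and scored for T quantitative traits. The package treats each
plot-level observation as

$$ y_{ijt} = \mu_t + g_{it} + b_{jt} + e_{ijt}, $$

with genotype effect vectors $g_i \sim N(0, \Sigma_g)$ shared across
blocks, block effects $b_{jt} \sim N(0, \sigma^2_b\,\sigma^2_{e,t})$,
and plot errors $e_{ijt} \sim N(0, \sigma^2_{e,t})$ independent across
traits and plots. The two-way fixed-layout ANOVA (genotype + block, no
interaction — the interaction is the error stratum of an RCBD) yields
the classical expected mean squares
$E[MS_G] = \sigma^2_e + r\,\sigma^2_g$, so the method-of-moments
components are

$$ \hat\sigma^2_e = MS_E, \qquad
   \hat\sigma^2_g = \frac{MS_G - MS_E}{r}, \qquad
   \hat\sigma^2_p = \hat\sigma^2_g + \hat\sigma^2_e. $$

Blocks are treated as a fixed stratum; no REML or mixed-model fit is
attempted. This is deliberate: the downstream parameter definitions
(GCV, PCV, broad-sense heritability, genetic advance) are defined on
exactly this decomposition, and the balanced design makes the
method-of-moments estimator the textbook companion.

A negative $\hat\sigma^2_g$ (possible when the genotype signal is weak)
is truncated to zero for all downstream parameters — otherwise GCV
would be imaginary — but the raw value is preserved in
`sigma2_g_raw` and a `W-NEGVAR` warning is emitted, so the truncation
is never silent.

## Genetic parameters

* `GCV = 100·σ_g/mean`, `PCV = 100·σ_p/mean` (percent; mean must be
  positive). Trait means always come from the data or the simulation
  config, never from an external table.
* `h2b = σ²g/σ²p`, classified low (< 0.50), medium (0.50–0.80,
  boundaries inclusive — the conventional "50–80%" phrasing is
  ambiguous at its endpoints, and assigning both to medium keeps the
  classes exhaustive without a hidden open interval), high (> 0.80).
* `GA = K·h2b·σ_p` with K = 2.06, the standardized selection
  differential at 5% selection intensity. K is a tabulated constant of
  truncation selection, not an estimate. GA uses the *unrounded* h2b:
  reproducing published genetic-advance values to three decimals fails
  if heritability is rounded first.

## Component correlations

Genotypic correlation is a correlation of genotype effects, not of
phenotypes. The package estimates cross-strata mean cross-products by
the sum-trait identity — run the same ANOVA on the synthetic trait
x + y, then `MCP(x,y) = [MS(x+y) − MS(x) − MS(y)]/2` per stratum —
which reduces exactly to the variance decomposition on the diagonal.

Two numerical choices matter:

* **Raw components in the denominators.** The phenotypic denominator
  uses $\hat\sigma^2_{g,\text{raw}} + \hat\sigma^2_e =
  (MS_G + (r-1)MS_E)/r$, which is always positive, and the genotypic
  denominator uses the raw genotypic component. This keeps the
  estimator coherent: an exact affine duplicate of a trait gives
  rg = rp = 1 identically. Traits whose raw genotypic component is
  ≤ 0 have no defined genotypic correlation; their rg rows are NA with
  a diagnostic rather than a fabricated value.
* **Clamping, not dropping.** Method-of-moments ratios can leave
  [−1, 1]. Entries are clamped to the boundary, flagged
  (`clamped_flags`, warning `W-CLAMP`), and the pre-clamp values kept.
  Boundary correlations are a real feature of nearly collinear trait
  sets (moisture / carbohydrates / calories in proximate panels), so
  they are surfaced, not hidden. Clamping never changes a sign.
  Floating-point overshoot below 1e-12 is clamped without flagging.

Significance is available for phenotypic correlations only (t with
G − 2 df); no agreed small-sample distribution exists for
component-level genotypic correlations, so none is invented.

## Path analysis

Direct effects P solve `R P = r` exactly (LU solve, no ridge, no
pseudo-inverse). With nearly collinear predictors the system is
ill-conditioned and |P| can exceed 10 or more — that is the honest
answer to the question being asked, and damping it would change the
decomposition's meaning. Instead the package:

* reports the condition number of R and warns (`W-COLLIN`) above 1e4;
* rejects exactly singular systems (relative eigenvalue below 1e-12),
  naming the null-space direction, because direct effects are then
  non-identifiable;
* enforces the row identity `P_i + Σ_{j≠i} R_ij P_j = r_i` to 1e-10 —
  it restates the linear system, so any violation is a solver bug, and
  published tables that break it (by rounding entries of very
  different magnitudes) are not imitated;
* reports `residual = sqrt(1 − Σ P_i r_i)`; ill-conditioning can push
  `1 − Σ P r` below zero, in which case the residual is reported as 0
  with `residual_clipped = TRUE` and the raw value retained.

## Multivariate stage

PCA is an eigen-decomposition of the trait correlation matrix of
genotype means (standardized variables), so eigenvalues sum to the
number of traits; each loading vector is flipped so its
largest-magnitude entry is positive, a pure reporting convention.

K-means is Lloyd's algorithm from k-means++ starts (best of
`n_restarts`, default 10, deterministic given `seed`), with the
objective asserted non-increasing at every iteration and an emptied
cluster re-seeded at the point farthest from its centroid. The
in-loop monotonicity assertion and the documented repair are the
reason the clustering loop is implemented in the package rather than
delegated; `stats::kmeans` serves as an independent quality check in
the test suite. Silhouette widths use Euclidean distance with the
singleton convention S = 0; `cluster::silhouette` is the test oracle.
The default k = 8 follows the reproduction report this package was
built around; silhouette averages are reported per cluster so a poor
k is visible rather than silently accepted.

## The synthetic-trial generator

No raw plot-level data are published for the panel this package
emulates, so `carrot_panel_config()` reconstructs the study conditions:
64 genotypes, 3 blocks, 15 traits, per-trait genotypic and error
variances set to the published component estimates, and trait means
back-calculated as `100·σ_g/GCV` from the published coefficients of
variation — the only reading of the printed coefficients that is
internally consistent (the printed GA-percent-of-mean row implies
different means and is not used). Error components printed as 0 are
below the table's resolution and are floored at 1e-4 so every trait
keeps a non-degenerate error stratum. The published beta-carotene
genotypic variance is internally inconsistent with its own mean
square; the config copies the printed component row and the
inconsistency is simply inherited by the emulation, not repaired.

The genotypic correlation structure encodes the reported sign pattern
(TSS–moisture +0.59, TSS–vitamin C −0.48, the
moisture/carbohydrates/calories trio at the ±0.98–0.99 boundary, the
protein–ash/fat/fiber block) plus the entries that boundary trio
logically implies; requested correlations are clipped to |r| ≤ 0.99
and the matrix projected to the nearest positive semi-definite
correlation matrix (eigenvalue clipping with diagonal rescaling,
iterated). The projection deliberately preserves the near-collinearity
that makes the path analysis ill-conditioned in character.

Design choices worth stating:

* **Block variance** is never published; the default multiplier
  σ²b = 0.1 (block effects at 10% of each trait's error variance) is
  small but nonzero so the block stratum is genuinely exercised;
  configurable.
* **Errors are independent across traits** (diagonal error
  covariance): no error covariances are published, and the simplest
  model consistent with the printed data avoids inventing structure.
* **No truncation to physical ranges**: percentages may stray outside
  [0, 100] in extreme draws. Truncation would bias the
  variance-component recovery checks, which is exactly what the
  generator exists to validate.
* Multivariate-normal draws use an eigendecomposition square root
  because Σg sits deliberately close to singular.

What the generator does *not* emulate: multi-year structure and
genotype-by-environment interaction (the emulated trial is a single
environment), non-normal trait distributions, spatial field trends
within blocks, and measurement rounding. Passing recovery tests
therefore show the estimators are correct under the stated model, not
that real field data meet the model.

## Problem sizes and numerics

The test suite validates the ANOVA strata against a brute-force
double-loop oracle on 1,000 random tables of up to 5 genotypes x 3
blocks (equality to 1e-9 relative), recovers h²b to ±0.03 and σ²g to
±5% from 200 simulated 64 x 3 trials at true h² = 0.8, and checks
correlation recovery with 100-trial Monte-Carlo means (±0.03). These
sizes give Monte-Carlo standard errors several times smaller than the
asserted bands while keeping the default suite under a minute.
Degenerate inputs have defined behaviour throughout: constant
responses yield all-zero mean squares with F = 0 by convention,
missing cells are an error (the design algebra assumes balance, and
imputation would bias components), and zero-variance traits are
rejected by name where standardization or correlation requires
variance.

## Derived-trait arithmetic

Carbohydrates are computed by difference,
`100 − (ash + moisture + fat + fiber + protein)`; the difference
formulation is the standard proximate-analysis convention. Calories
use Atwater factors 4/9/4 (kcal per 100 g — the per-100 g basis is a
convention, as compositional inputs are percentages). Protein is
Kjeldahl nitrogen x 6.25. Colour difference is the Euclidean ΔE*ab in
CIE 1976 L\*a\*b\*. DPPH inhibition is the fractional 517 nm
absorbance drop, scale-invariant in absorbance units. Inconsistent
inputs (components summing past 100, absorbance gain over incubation,
protein ≥ 100%) are flagged (`W-QC`) rather than rejected, so batch QC
of noisy laboratory panels proceeds with a report instead of dying on
the first bad row.

## Known limitations

* Single-environment RCBD only; no combined multi-year analysis.
* Broad-sense heritability only; no narrow-sense or realized
  heritability.
* Genotypic correlations carry no significance test, by design.
* Path analysis has no standard errors; it is a decomposition, not an
  inferential model.
* The pipeline's interface is the R function surface; file-based
  composition is available through the CSV/JSON readers and writers
  each stage exposes.
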