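---
title: "Methods: delta-gamma spatial dynamic factor analysis for mixed fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-gamma spatial dynamic factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mixed demersal fisheries catch many species in the same tow. Managing them
under catch quotas requires knowing which species co-occur, how stable
their spatial association is from year to year, and where (and with which
gear) catches of a pair can best be separated. `sdfa` addresses this with a
joint dynamic species distribution model: a delta-gamma (hurdle)
observation model whose two components — encounter probability and
positive catch density — are each driven by a small number of shared
latent spatial fields through species-specific factor loadings.

For a haul at knot $s$, year $t$, survey $v$, species $c$:

$$\mathrm{logit}\, p = \beta_p(c,t) + \sum_f L_{\omega p}(c,f)\,\omega_p(s,f)
 + \sum_f L_{\varepsilon p}(c,f)\,\varepsilon_p(s,f,t) + \delta_p(c,v)$$

$$\log r = \beta_r(c,t) + \sum_f L_{\omega r}(c,f)\,\omega_r(s,f)
 + \sum_f L_{\varepsilon r}(c,f)\,\varepsilon_r(s,f,t) + \delta_r(c,v)
 + \log a_i$$

with catch $C = 0$ with probability $1-p$ and otherwise gamma-distributed
with mean $r$ and per-species shape $k$. The $\omega$ fields are
time-invariant ("average" spatial) factors, drawn once; the $\varepsilon$
fields are spatiotemporal factors, drawn independently per year. Each
factor field is a unit-variance Gaussian Markov random field over the knot
grid with Matérn correlation and geometric anisotropy; equivalently, the
stacked species-space process is matrix-normal with covariance
$R \otimes LL^\top$, which is how both the pure-R likelihood
(`matrix_normal_logpdf()`) and the compiled objective evaluate it without
forming the Kronecker product.

Assumptions worth stating plainly: hauls are conditionally independent
given the latent fields; fields are piecewise constant at the knot
resolution (each haul maps to its nearest knot); species interact only
through shared factors (no direct interaction terms); catchability differs
by survey and species but not over time; and the year-by-species intercepts
are unsmoothed fixed effects.

## Parameters that matter

* **Factor counts** (per component): how much among-species covariance
  structure is estimable. The configuration default of 9 follows common
  practice for ~18 species-size classes; desk-scale analyses in the test
  suite use 1–2 factors for 2–4 species. Counts above the species number
  are rejected.
* **Matérn inverse range `kappa`** (1/km), separately for the encounter and
  density components, parameterized in the configuration through the
  *decorrelation range* — the distance (km) at which correlation falls to
  10%. Defaults are 97 km (encounter) and 140 km (density), typical of a
  shelf-sea demersal community, on a default domain of 715 km × 445 km.
  `kappa` is estimated by default (`estimate_kappa = TRUE`).
* **Smoothness `nu`**: fixed at 1, the usual SPDE-approach choice; it is
  not estimable from realistic survey data and the compiled likelihood
  supports only `nu = 1`. The R-side Matérn functions accept any `nu`
  (used, e.g., for the exponential special case `nu = 0.5` in tests).
* **Anisotropy `h1`, `h2`**: a two-parameter unit-determinant metric
  $H = [[e^{h_1}, h_2], [h_2, (1+h_2^2)e^{-h_1}]]$, so the area of any
  correlation ellipse is preserved. Off (isotropic) by default; estimable
  via `estimate_anisotropy = TRUE`.
* **Gamma shape `k`** (per species): positive-catch variability,
  CV $= 1/\sqrt{k}$. Generator default 1 (CV 100%, typical of trawl catch
  weights); recovery experiments use 1.5.
* **Swept-area offset**: `log(area)` enters the *density* predictor only —
  catch scales with area swept while encounter probability is treated as
  area-free. Whether swept area should instead enter as a free covariate is
  genuinely open; the offset is the standard delta-model convention and is
  a configuration switch (`offset_density`).

## The synthetic-data generator

`simulate_truth()` + `simulate_survey()` generate surveys with *exactly*
the model's structure: intercepts and catchability effects from the normal
priors recorded in the configuration, GMRF factor fields from the same
Matérn machinery the likelihood uses, Bernoulli encounters and gamma
positive catches. Defaults emulate a Celtic-Sea-like setting: 18
species-size classes, 26 years, 7 surveys, a 715 × 445 km planar domain
(equirectangular km projection, since ranges are naturally quoted in km),
250 knots, lognormal swept areas with median 0.05 km².

Planted assemblage structure uses block loadings: each factor is assigned
a dominant species block with loading magnitude 1.0 against 0.2 elsewhere,
with the factor's overall sign random and off-block signs random per entry
— giving high within-block and weak between-block correlation, the
qualitative structure of roundfish/flatfish/deeper-water communities.

What the generator does **not** emulate — and hence what passing recovery
tests cannot show about real data: gear physics and tow tracks, non-gamma
catch distributions (e.g. haul-level overdispersion beyond the shape
parameter), density covariates (depth, substrate) acting directly rather
than through latent fields, model misspecification of the Matérn family,
and non-random station placement (real surveys are depth-stratified).

## Estimation and numerical choices

The latent fields are integrated out by Laplace approximation: an inner
Newton optimization over all field values (TMB, automatic differentiation,
sparse inner Hessian), nested in an outer `nlminb` quasi-Newton over fixed
effects (default `rel.tol` 1e-8, up to 1000 iterations). In the
linear-Gaussian limit (identity link, normal errors — exposed as the
`family = "gaussian"` validation hook) the approximation is exact, and the
test suite checks it against the closed-form integrated likelihood to
1e-6; the same suite checks the automatic gradients against finite
differences of the independent pure-R likelihood to 1e-5.

* **Identifiability**: loading matrices are lower-triangular during
  estimation (any rotation of $L$ with counter-rotated fields leaves the
  likelihood unchanged — itself a test). Column signs are normalized
  *after* fitting (largest-magnitude loading positive, fields
  counter-flipped) rather than constraining diagonals non-negative during
  optimization: a hard non-negativity constraint puts null-ish fits on a
  constraint boundary and degrades the outer Hessian, while the post-hoc
  flip is likelihood-invariant.
* **PD jitter**: 1e-8 on correlation-matrix diagonals before factorization;
  rank deficiency of $LL^\top$ when factors < species is expected and
  handled the same way.
* **Starting values**: intercepts from empirical per-species-year encounter
  frequencies (clamped to [0.02, 0.98]) and mean positive densities;
  loadings N(0, 0.1²) under a start seed; fields zero. `n_starts` restarts
  keep the best marginal NLL; restart stability (NLL spread < 0.5) is
  tested.
* **Reference levels**: the first survey's catchability is fixed at 0 per
  component (otherwise confounded with intercepts). Density surfaces and
  abundance indices are computed at this reference (gear-free); gear
  effects appear only in `catch_composition()`.
* **Conventions**: a fish exactly at the size-class cutoff counts as adult;
  hauls with all-zero catches are retained (informative zeros); surface
  standardization is z-scoring across knots within species-year (min-max
  available), so "difference maps" compare *relative* spatial pattern, not
  absolute density; clustering uses average linkage on distance
  $1 - \rho$ with ties broken by species order (linkage is an argument).
* **Expected density** is the delta-gamma mean $p \cdot r$ (closed form,
  standard for index construction), not the median.
* **Information criteria**: AIC $= 2m + 2\,\mathrm{NLL}$,
  BIC $= m\log n + 2\,\mathrm{NLL}$ with $m$ the fixed-effect count and
  $n$ the number of haul × species rows.

## Problem sizes

The test suite and the reproduction script run entirely on desk-scale
simulations chosen so the full suite completes in minutes on one CPU:
the central recovery experiment uses 4 species (2 planted assemblages),
2 factors per component, 30 knots, 10 years, 2 surveys × 150 hauls/year
(3000 hauls, 12 000 observations, 122 fixed effects, 1320 latent values);
the null-calibration experiment uses 20 replicate fits of 3 species,
2 factors, 20 knots, 4 years × 250 hauls on a 700 × 450 km domain. The
full-size configuration (250 knots, 18 species, 9 factors, 26 years) is
accepted by the same code path but is a cluster-scale computation.

## Known limitations

* **Wald CIs at boundary optima.** The correlation CI machinery propagates
  the asymptotic normal of the loading estimates through 500 Monte-Carlo
  draws (SE = draw SD, CI = estimate ± 1.96 SE). When data carry *no*
  factor signal, roughly half to two-thirds of maximum-likelihood fits
  collapse to rank-deficient loadings whose implied correlations sit
  exactly at ±1 — a boundary of the parameter space where Wald machinery
  is known to be anti-conservative. In repeated null simulations the CI
  masks about 80–87% of truly-zero correlations rather than the nominal
  ~95%, and this does not improve with sample size (the collapse
  probability is an O(1) boundary-mixture weight). Away from the boundary
  — true-zero pairs inside a model with real signal elsewhere, the
  situation matching real communities — masking is well calibrated
  (≥ 90% in the test suite). Interpret significance of correlations from
  fits whose loadings are near rank-deficient with caution.
* The Laplace approximation is unverified (beyond gradient and
  linear-Gaussian checks) for severely zero-inflated species; very low
  encounter rates can make the inner problem ill-conditioned.
* Knot-level piecewise-constant fields understate fine-scale gradients;
  prediction products are knot tables for an external GIS, with no
  cartography here.
* Abundance-index SEs propagate fixed-effect uncertainty with fields held
  at their modes; they omit field uncertainty and are therefore slightly
  optimistic.
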