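---
title: "Chemometric optimization of QuEChERS soil extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric optimization of QuEChERS soil extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quechersrsm)
```

## The problem

Recovering cyclohexanedione oxime (CHD) herbicides — alloxydim, sethoxydim,
profoxydim — and their degradation products from soil with a QuEChERS
("quick, easy, cheap, effective, rugged, and safe") procedure depends on
five interacting extraction variables: soil weight (SW, g), the
acetonitrile proportion of the acetonitrile/methanol extraction mixture
(AM, %), extraction solvent volume (EV, mL), added water (WC, mL) and
extraction time (ET, min). Optimizing them one at a time is slow and blind
to interactions, so this package implements the response-surface route: a
designed experiment over all five variables, an empirical polynomial
recovery model per compound, and a search over the modelled surface for
conditions that bring every compound's predicted recovery to a target.

## The design

Each variable is *coded* from its working range $[low, high]$ onto
$[-1, +1]$ via $x = (u - \bar{u}) / h$ with centre $\bar{u} = (low+high)/2$
and half-range $h = (high-low)/2$. Coding makes fitted coefficients
directly comparable across variables with very different units.

The experiment is a face-centred central composite design (CCF): the full
$2^k$ factorial (all coordinates $\pm 1$), $2k$ axial points on the face
centres (one coordinate $\pm 1$, axial distance $\alpha = 1$, so only three
levels per factor are ever used), and replicated centre points carrying
pure replicate error. With $k = 5$ factors and three centre points this is
$2^5 + 2\cdot5 + 3 = 45$ runs per extraction system, i.e. 90 conditions
across the citrate- and acetate-buffered systems.

```{r}
space <- chd_factor_space()
design <- ccf_design(space, n_center = 3)
design
```

Run order is deterministic (factorial block in lexicographic order, axial
pairs, then centres). The experiments this emulates were not described as
randomized, and a fixed order keeps every simulated table reproducible;
randomizing run order is out of scope because the model has no run-order
term to estimate.

## The recovery model

Per compound, recovery is modelled as

$$Y = b_0 + \sum_i b_i X_i + \sum_i b_{ii} X_i^2
      + \sum_{i<j} b_{ij} X_i X_j + \sum_{i<j<k} b_{ijk} X_i X_j X_k,$$

a 31-term basis for five factors (intercept, 5 linear, 10 two-way, 10
three-way, 5 quadratic). The basis order is fixed everywhere — fitting,
printing, CSV serialization — so coefficient tables round-trip exactly.

Fitting is ordinary least squares per compound, independently (the
responses are modelled separately; no multivariate structure is assumed).
With 45 runs and 31 terms the residual degrees of freedom are 14. Centre
replicates contribute pure error, but inference uses the pooled residual
variance of the single fit — no lack-of-fit decomposition — which matches
how a single least-squares regression per response is reported. Standard
errors come from the residual-variance-scaled inverse Gram matrix, and
each coefficient gets a two-sided t-test whose p-value is annotated with a
confidence-level letter: `a` (95%, p < 0.05), `b` (90%), `c` (80%), `d`
(70%), blank otherwise. The t-test is the standard convention for
coefficient significance in response-surface work; the letters in the
shipped coefficient tables are consistent with it. Goodness of fit is the
multiple correlation coefficient $R = \sqrt{1 - SSE/SST}$.

Rank deficiency is detected explicitly (smallest-to-largest singular value
ratio below $10^{-10}$) before solving, because a truncated or badly
subsetted design can silently alias quadratic terms.

```{r}
tab <- simulate_recoveries(design, quechers_coefficients("citrate"),
                           noise_sd = 2, seed = 1)
fit_full_model(tab, "alloxydim")
```

## Term removal and the deviation audit

Simpler equations are attractive, but removing "non-significant" terms can
distort predictions — in particular the intercept anchors the response at
the design centre. `prune_model()` retains the intercept plus all terms at
or above a minimum confidence level (95, 90, 80, 70, or 0 = full
equation). The default mode is **truncate**: dropped terms are deleted and
the surviving coefficients keep their full-fit values. This evaluates the
simplified equation exactly as one would use it after crossing terms out
of a printed table, which is the scenario the audit is about; a **refit**
mode (reduced basis refitted) is available for comparison. Whether one
refits after removal is genuinely open; truncation was chosen as the
default because the audit's purpose is to test the printed equations'
robustness to deletion, not to build a new model.

`selection_report()` tabulates, per compound and level, the range of
absolute deviations $|predicted - observed|$ in recovery percentage points
together with the correlation R between predictions and observations.
Deviations are absolute (not relative) percentage points: recoveries
already live on a percent scale near 100, and residual-scale magnitudes
are what an analyst compares against acceptability bands. The two columns
deliberately sit side by side: a wide response range can hold R high while
individual runs sit far from the surface, so R alone cannot certify a
simplified model — the tests construct exactly such a case (strong AM
trend plus one outlying run) and require the report to expose it.

## Optimizing the extraction conditions

`optimize_conditions()` searches the coded cube $[-1,+1]^5$ — never
outside it, because an empirical polynomial has no validity beyond the
studied region — for conditions where every compound's predicted recovery
falls within a tolerance band around the target (default $100 \pm 2.5$
recovery points; the band matches the spread of the predicted values the
selected conditions achieve, 97.6–100.1). Among feasible points the solve
is lexicographic: minimize the unweighted sum of scaled factor positions
$(u - low)/(high - low)$, i.e. prefer the minimum values of all variables
(less soil, solvent and time per analysis). The surfaces are degree-3
polynomials that can carry multiple optima, so a dense grid scan (default
21 points per axis, evaluated in memory-bounded chunks) runs first and a
constrained Nelder–Mead polish refines the best grid point. If no feasible
point exists the minimizer of the worst-case deviation is returned,
flagged infeasible.

The weighting across the five variables in the tie-break is not prescribed
anywhere; the unweighted scaled sum is the neutral choice. Consequently
the optimizer is guaranteed to return *a* feasible, prediction-matching
point, not the specific published condition set — the published citrate
point is itself verified feasible by the tests.

```{r}
opt <- optimize_conditions(quechers_coefficients("citrate"), space,
                           target = 100, tolerance = 2.5, n_grid = 11)
opt
```

## Matrix effect

For LC-MS quantification, co-extracted soil components suppress or enhance
ionization. The matrix effect compares calibration slopes measured in pure
solvent ($S_s$) and in blank matrix extract ($S_m$) over the linear range
0.005–0.1 mg L$^{-1}$:

$$ME(\%) = \frac{S_m - S_s}{S_s} \cdot 100,$$

negative for suppression, positive for enhancement, and flagged
significant when $|ME| > 20\%$ — a fixed decision rule of the field, not a
statistical test, so no slope-comparison test is added. Slopes are
unweighted OLS with an intercept (forcing the line through zero would bias
the slope under any baseline offset). `me_panel()` applies this per
compound across extraction/clean-up combinations (citrate/acetate alone or
with PSA or PSA–C18 dispersive clean-up).

## The synthetic-data generator

The raw per-run recovery tables behind the shipped coefficient fixtures
are not available, so `simulate_recoveries()` generates them:
$Y = \beta^\top f(x) + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$,
homoscedastic across runs, clipped below at 0 (recoveries cannot be
negative; there is no upper clip because observed recoveries above 110% do
occur). Gaussian homoscedastic noise is the simplest structure consistent
with unweighted least-squares fitting; $\sigma = 2$ recovery points is the
default, a replicate error plausible for the published scatter, and it is
a free parameter, not an estimate. The default ground truth in tests is
the shipped coefficient tables themselves, so simulated studies inhabit
the real surfaces' geometry (including the saddle behaviour of the acetate
sethoxydim surface in AM × EV). `simulate_calibration()` plays the same
role for the matrix-effect stage: a solvent series plus a matrix series
whose slope encodes a known ME.

What the generator does **not** emulate: heteroscedastic or non-Gaussian
replicate error, run-order drift, matrix-dependent noise, or any soil
chemistry. Passing tests therefore demonstrate the statistical machinery
is correct under the stated error model, not that the fitted equations
describe any particular soil.

## Numerical choices and problem sizes

* Coding/decoding are exact linear maps; round-trips are tested to
  $10^{-12}$.
* The QR fit is cross-checked against an independent normal-equations
  solve to $10^{-8}$ on random tables.
* Monte Carlo checks use 200–500 replicates of the 45-run design — large
  enough that empirical standard errors settle within the 15% assertion
  band, small enough that the whole suite runs in seconds.
* Grid resolutions: 21 points per axis (about 4.1 million candidate
  points, evaluated in chunks) for production optimization; tests use 5–11
  points where only feasibility or tie-breaking is at stake.
* Degenerate inputs fail loudly: empty factor spaces, zero-width ranges,
  rank-deficient designs, recovery tables with negative or non-finite
  entries, calibration series with fewer than 3 points or zero
  concentration spread, and a zero solvent slope.

## Known limitations

* The deviation audit can only be reproduced *in distribution*: the
  published deviation table depends on the unavailable raw recoveries, so
  the package validates the audit's structural properties (SSE
  monotonicity, nesting across levels, level-0 identity) on synthetic
  tables instead of its printed numbers.
* Truncate-mode R is a plain correlation and is reported as `NA` when
  either side is constant (e.g. an intercept-only pruned model).
* The optimizer's tie-break is one defensible reading of "minimum values
  of the variables"; alternative weightings would select different, equally
  feasible points.
* Inference assumes homoscedastic Gaussian residuals; no lack-of-fit test
  against pure error is provided.
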