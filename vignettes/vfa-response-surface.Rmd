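---
title: "Methods: cubic response surfaces, grid optima and bootstrap inference for VFA production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cubic response surfaces, grid optima and bootstrap inference for VFA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfasurf)
```

## The experimental structure

The package models total volatile fatty acid (VFA) production, in mg COD/L,
from anaerobic batch fermentation of wastewater sludge.  The study design it
encodes crosses two sludge types at two organic loads each (digested sludge
at 4 and 6 g VS/L, primary sludge at 10 and 14 g VS/L) with three initial pH
levels (9.5, 10.5, 11.5) and four incubation temperatures (25, 35, 45,
55 °C): 48 combinations, each sampled destructively in triplicate every
3 days.  Runs at 25–45 °C last 12 days; at 55 °C methane onset ends the
experiment at 9 days ("methane censoring").

Temperature is a *continuous* covariate, not a treatment factor: the 48
combinations collapse to 12 discrete treatments (sludge × load × pH), each
modelled as a smooth surface over temperature and retention day.
`vfa_design()`, `vfa_treatments()` and `design_days()` encode this;
`read_observations()`/`write_observations()` move validated replicate-level
tables through a fixed CSV dialect with explicit units (mg COD/L, g VS/L,
°C, days).  Units are fixed in the schema deliberately — silent unit errors
dominate this domain — and replicate indices are explicit so duplicate rows
are detectable.

Day-0 rows are accepted by the schema (`day >= 0`) and optionally generated
(`include_day0 = TRUE`), but excluded from the default design: VFA at
inoculation is a baseline, and forcing the cubic through an arbitrary
intercept interpretation is avoidable.  Whether day 0 was assayed per
reactor in the original study is not decidable from its report; both
interpretations remain expressible.

## The response-surface model

Each treatment's response is a full bivariate cubic,

$$\mathrm{VFA}(t, d) = \beta_0 + \beta_1 t + \beta_2 d + \beta_3 t^2 +
\beta_4 t d + \beta_5 d^2 + \beta_6 t^3 + \beta_7 t^2 d + \beta_8 t d^2 +
\beta_9 d^3,$$

fitted by ordinary least squares to the replicate-level points of that
treatment (`vfa_surface()`).  Two modelling commitments matter:

* **Replicates are individual rows**, never averaged.  Consequently r² is
  computed against replicate scatter: with within-cell noise of ~516
  mg COD/L, even a surface passing exactly through every cell mean cannot
  reach r² = 1.  Values around 0.7–0.9 on realistic noise are the expected
  regime, which is exactly why the downstream significance testing exists.
* **The quadratic model of classical response-surface methodology is not
  assumed sufficient.**  The temperature range (30 °C) and horizon (12 d)
  are wide, and the response is rich enough that third-degree terms carry
  real structure.  `compare_degrees()` fits degrees 2, 3, 4 on the same data
  and reports r², adjusted r² and residual df; `pareto_tvalues()` ranks the
  ten coefficient |t|-values against the two-sided critical t at the fit's
  residual df (2.052 at df 27, α = 0.05) — significant cubic terms justify
  the degree choice.

One structural caveat the degree comparison makes visible: a *full* quartic
(15 terms) needs five distinct levels per axis, while the design has four
temperatures (and four sampling days without day 0).  On design-shaped data
the degree-4 fit correctly refuses with a rank-deficiency error naming t⁴;
quartic checks therefore belong on data with five levels per axis, which the
test suite generates.

### Numerical conditioning

Raw cubic monomials at t ≤ 55 make the normal equations hopeless
(κ(XᵀX) ≈ 7·10¹³ on the study design).  The fit therefore centres and
scales t and d internally, solves by QR on the scaled basis, and maps
coefficients and covariance back to the raw monomial scale through the exact
binomial-expansion transform, so reported β's are directly comparable across
treatments while the solve stays stable.  Coefficient t-values use the
classical homoscedastic OLS covariance with n − 10 residual df.  Degenerate
inputs fail loudly with classed errors: fewer than 11 rows
(under-determination), collinear level structure (singularity naming the
offending columns).

## Locating the optimum

`sweep_optimum()` evaluates the fitted surface on an exhaustive lattice
(default 0.05 °C × 0.05 d, ~1.4·10⁵ points) over the feasible domain and
returns the maximizer.  Gradient methods are deliberately absent: the
censored domain makes a sweep simpler, and 0.05 resolution is far below
experimental precision.  Ties break toward the lowest temperature, then the
lowest day — the cheaper operating condition.  Grid points are generated as
`min + k·resolution`, so nested resolutions share lattice points and
refining the lattice can only raise the located maximum.

The censoring shape above 45 °C is not determined by a 4-level temperature
design; `study_domain()` offers a step rule (12 d up to 45 °C, 9 d above —
the default, adding no invented information) and a linear taper between 45
and 55 °C.  The default day range starts at 0 because the polynomial is
defined on the full horizon, but note that days 0–3 are unsampled: the cubic
*extrapolates* there, and fitted maxima on that edge are high-variance (see
the calibration section).  Sweeping `day_range = c(3, 12)` restricts the
optimum to the sampled horizon and is what the examples use.

## Bootstrap uncertainty of the optimum

The optimum is a maximum of a fitted surface — no closed-form standard error
is credible.  `bootstrap_optima()` instead propagates uncertainty through
the whole chain: B times (default 300, the study's choice), draw a
pseudo-dataset, refit the cubic, re-sweep, store the optimum.

The pseudo-data model is the one the analysis already assumes: equal, normal
replicate variability at every experimental end point.  Each cell's
replicate values are redrawn as the cell's **observed mean** plus Gaussian
noise at the treatment's **pooled within-cell SD**, truncated at zero.
Centring on cell means makes the fewest model assumptions; a model-based
variant centring on fitted values is one flag away (`center = "fitted"`,
also available as the `simulate()` method of a fit).  Pooling the SD is
forced by the 2-replicate-minimum cells; truncation bias is negligible at
the ~3000+ mg COD/L means the generator produces (≥ 4σ from zero).  Singular
refits (essentially impossible on the fixed design, possible on degenerate
user data) are retried up to 5 times with fresh noise, then error; retry
counts are recorded.  The full resample→fit→sweep chain is deterministic
given the seed.

The bootstrap mean of the optimal VFA is biased *upward* relative to the
truth's feasible maximum — the winner's curse of taking a maximum over a
noisy surface.  The test suite asserts this bias is non-negative rather than
hiding it; users comparing bootstrap means to point predictions should
expect the gap.

## Between-treatment inference

**ANOVA with regression-adjusted df** (`anova_optima()`).  The B bootstrap
optima per group are not B independent observations; the information behind
each group is bounded by its regression's residual df.  The ANOVA therefore
takes `df_per_treatment` explicitly: within-group df is k·m (12 × 28 = 336
in the study's table), and sums of squares are scaled as if each group had
m + 1 observations, keeping MS_within equal to the pooled bootstrap
variance.  `df_per_treatment` is a parameter rather than a derived constant
because the study's own df bookkeeping is internally inconsistent (a t
threshold of 2.052 implies df 27; its t-test table prints df 28), and
because whether its ANOVA consumed all 300 optima or a df-sized subsample is
not stated — the parameter expresses every reading.  The study's printed
between/within/total SS values are likewise not mutually consistent under
any parsing; the package reproduces the *procedure* and the critical value
(F₀.₀₅;₁₁,₃₃₆ = 1.817), not the unreproducible table entries.

**Top-two t-test** (`t_test_top_two()`).  The two treatments with the
highest mean optimal VFA are compared by a pooled-variance two-sample t
(equal variance is the bootstrap's own assumption; Welch is optional), again
with m df per group, i.e. effective n = m + 1.  The critical value uses
df₁ + df₂, which preserves the exact two-group identity F = t² with
`anova_optima()`; the familiar 2.052 threshold (single-regression df 27) is
available directly via `critical_t()`.

No multiple-testing correction is applied across the 12 treatments, by
design: the workflow tests one planned global hypothesis (ANOVA) and one
planned pairwise comparison.

## The synthetic-data generator

`simulate_study()` emulates exactly the statistical structure the analysis
assumes: a known cubic truth surface per treatment plus i.i.d. Gaussian
replicate noise, truncated at zero, on the factorial design with 55 °C
censoring.  The default noise SD of 516 mg COD/L is the replicate SD the
study reports repeatedly alongside its best measurements.

Truth surfaces are generated in an interpretable peak parameterization —
peak location (t₀, d₀), peak height H, baseline, curvature shares, small
third-order distortions — and expanded symbolically to monomial
coefficients.  Sampling raw β's almost never yields bounded, realistic
surfaces; the peak form makes parameter-recovery tests meaningful.  Budget
constraints keep each surface within [0, 7500] mg COD/L (verified on a
dense grid, with deterministic shrinkage if exceeded) and feasible maxima in
[3000, 7500].  The designated best treatment (PS, 14 g VS/L, pH 10.5) gets a
fixed peak: ~7000 mg COD/L near 26 °C and 7.3 days, so default pipelines
land in the region the study reports (optimum ~6975 mg COD/L at 25 °C /
7.3 d); all other treatments peak at 3500–6500 mg COD/L at seeded random
locations, strictly below the best.

One behaviour worth flagging: raw-monomial bases are highly collinear, so
individual coefficient standard errors are large even when the surface as a
whole is well determined.  Under the generator's default effect sizes and
noise, Pareto charts therefore often flag few or no individual terms at
α = 0.05 despite r² ≈ 0.7–0.8 — per-term significance on this basis requires
strong signal, and a sparse Pareto chart on one dataset is not evidence
against the surface fit itself.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: heteroscedastic replicate noise (the study's
figures hint error bars vary across cells, but its own bootstrap assumes
equal variance, which the generator mirrors); any mechanistic fermentation
kinetics (lag phases, substrate depletion, pH drift, methanogen
competition); day-0 dynamics; and correlation between cells sharing a
reactor batch.  Conclusions about method calibration transfer to real data
only to the extent the homoscedastic-Gaussian-around-a-cubic approximation
holds.

## Calibration choices and problem sizes

The test suite checks the statistics, not just the code paths, at sizes
chosen to keep the full suite under a minute:

* ANOVA type-I error: 500 null simulations (4 groups × 10), rejection rate
  within 0.05 ± 0.02.
* Coefficient 95% CI coverage: 200 synthetic fits at noise SD 516 on the
  study design; coverage within 95% ± 4%.
* Pareto type-I: 500 constant-truth fits; mean significant non-intercept
  terms ≈ 9α within 3 SE.
* Bootstrap SD of the optimum: one dataset bootstrapped at B = 100 versus
  the SD of optima across 200 fresh datasets from the same truth, within
  25%, at sweep resolution 0.25.

The bootstrap calibration runs on the sampled day horizon [3, 12].  On the
full [0, 12] domain the argmax functional is unstable: fitted maxima
sometimes land on the extrapolated day-0 edge where prediction variance is
large, and single-dataset bootstrap SDs then scatter several-fold around the
fresh-dataset SD.  Restricting to the region with data makes the optimum a
stable functional and the calibration meaningful; the same restriction is
recommended (and used in the examples) when interpreting real optima near
the horizon edges.

## Known limitations

* The cubic is a descriptive surface, not a kinetic model; extrapolation
  outside the design region (below day 3, outside 25–55 °C) is statistically
  unguarded.
* With four temperature levels, t-direction curvature beyond cubic is
  unidentifiable, and even the cubic's t³ coefficient leans on only four
  support points.
* Pooled-SD parametric resampling understates uncertainty if real replicate
  noise is heteroscedastic or non-Gaussian.
* The adjusted-df ANOVA is a principled but approximate device: bootstrap
  optima within a group are exchangeable draws from one estimated sampling
  distribution, not independent measurements, and the df parameter encodes a
  judgement, not a theorem.
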