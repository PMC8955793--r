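---
title: "Methods: response-surface optimization of chiral electrokinetic separations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface optimization of chiral electrokinetic separations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qekc)
```

`qekc` models the enantiomer resolution (and total analysis time) of a
chiral electrokinetic chromatography separation as a quadratic function of
the separation factors, selects informative experiments by D-optimality,
and closes the loop with an electropherogram-level simulator so that the
whole pipeline — trace, peak, resolution, surface, prediction — can be
validated end to end without an instrument. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Factor coding

Each factor (applied voltage `U` in kV, maltodextrin concentration `MD`
in % w/v, background-electrolyte `pH`) is defined by a
`factor_domain(name, low, mid, high)` and coded as

$$x = \frac{\text{value} - \text{mid}}{(\text{high} - \text{low})/2},$$

mapping low/mid/high to $-1/0/+1$. The shipped amlodipine domains have
mids at the exact midpoints, so this equals the standard orthogonal
coding and coefficients of different factors are directly comparable.
Decoding is the exact inverse; values outside the domain code outside
$[-1, 1]$ and are treated as extrapolation rather than an error, because
method-transfer settings (e.g. a 20.7 kV instrument matched to a nominal
20 kV) legitimately sit slightly outside the box.

## Design selection

The candidate set is the full three-level factorial grid ($3^K$ points;
27 for three factors) — the natural candidate set when a "full factorial
reduced to $n$ combinations" design is wanted. `d_optimal()` maximizes
$\det(X'X)$ of the 10-term quadratic model matrix over $n$-run subsets by
single-point Fedorov exchange: from a random nonsingular start, every
(design point, candidate) swap is scored and the best accepted, until no
swap improves the determinant; the whole search restarts `n_starts` times
and keeps the best design. Exchanges are accepted only above a $10^{-9}$
relative gain and candidate ties resolve to the lowest index, so results
are reproducible under a fixed seed. Duplicated candidates are allowed —
replicated runs are legitimate in D-optimal design — although for the
default 15-run, 10-term instance the optimizer settles on 15 distinct
points with $\det(X'X) = 2.4192\times 10^8$ (D-efficiency
$100\det(X'X)^{1/p}/n \approx 46\%$), matching the information content of
the published 15-run design. D-optimal solutions are not unique, so the
package asserts determinant parity-or-better rather than recovery of one
particular run list. With $n$ below the number of model terms the
information matrix is singular by construction and selection refuses to
run.

The exchange is $O(\text{starts} \times \text{sweeps} \times n \times
N_\text{cand})$ determinant evaluations of a $p \times p$ matrix; at the
sizes this field uses (tens of candidates, $p \le 10$) direct evaluation
is faster to get right than rank-one updating, so no updating formulas
are used.

## Response-surface fitting and term pruning

`rsm_quad()` fits the full quadratic
$\hat y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
\sum_{i<j} \beta_{ij} x_i x_j$ by ordinary least squares via QR, on the
per-run *mean* response over replicate injections (the raw injections are
not part of the run table; degrees of freedom are $n_\text{runs} - p$).
Standard errors come from $s^2 (X'X)^{-1}$, p-values from two-sided
t-tests, and $\bar R^2 = 1-(1-R^2)(n-1)/(n-p)$. No multiple-testing
correction is applied, matching standard DoE practice.

Backward elimination (default $\alpha = 0.1$) drops the non-intercept
term with the largest $p \ge \alpha$, refits, and repeats until all
remaining terms are significant; ties resolve to the later term, and the
intercept is always retained. The reported model is the *refit* of the
reduced term set, not the full fit with zeroed entries: refitting is what
makes the reduced coefficients, their SEs and the residual RMSE
internally consistent. Elimination is iterative rather than single-pass
because a term that is masked in the full model (the quadratic voltage
term here) can become clearly significant once noise-only terms leave.

On the shipped 15-run amlodipine table this retains
$\{1, U, MD, pH, pH{\times}U, U^2, pH^2\}$ for resolution and the same
set minus $U^2$ for analysis time. A caveat documented in the tests: the
shipped table prints resolutions to two decimals, and that quantization
moves refit coefficients by up to $\sim 0.005$ (third significant
figure) relative to the originally reported table, and the
all-high-corner prediction from 1.50 to 1.51. The package reports what
the printed data support.

Predictions carry confidence or prediction intervals,
$t_{1-\alpha/2,\,df}\; s \sqrt{\delta + x'(X'X)^{-1}x}$ with $\delta=1$
for prediction intervals (the default: a new run's mean is what a method
developer will actually observe) and $\delta=0$ for confidence intervals;
both kinds are exposed because reported "±" values in method-transfer
tables rarely say which they are.

## Effect diagnostics

All diagnostics are pure functions of `predict()` on the fitted surface —
they contain no independent model math, which is itself asserted in the
tests.

* **Adjusted response**: the predicted response versus one factor with
  every other model column replaced by its mean over the actual design
  runs (interactions involving the profiled factor use level × design
  mean of the partner). Averaging over the design, not over the cube,
  matters: the design is not perfectly balanced (e.g. the mean coded pH
  is $-2/15$), and design-averaging is what reproduces the narrative
  "low-MD ≈ 1.3, high-MD ≈ 1.8" scale.
* **Pareto chart**: non-intercept terms ranked by $|t| = |\beta|/SE$,
  signed by the coefficient. The t scale, not the raw coefficient, is
  used because quadratic columns have a different scaling than main-effect
  columns on a three-level design ($\overline{x^2} \approx 0.8$ here) and
  only standardized magnitudes order effects fairly.
* **Interaction profiles**: response along one factor at three fixed
  levels of another, remaining factor at 0. The attached parallelism
  statistic — the largest deviation of the high-minus-low curve difference
  from its mean — is exactly $2|\beta_{ij}|$ for a quadratic surface and 0
  when no interaction is retained.
* **Contour panels**: the surface over two coded factors with the third
  fixed, on a 101×101 grid (fine enough that the panel minimum is within
  $\sim 10^{-4}$ of the true corner/edge minimum for these gentle
  quadratics), with the baseline-resolution iso-line $R_s = 1.5$
  extracted by `grDevices::contourLines` (marching squares with linear
  edge interpolation). `iso_contained` flags panels whose minimum clears
  the criterion — the "everything works here" region of the design space.

## Electropherogram measurement

`detect_peaks()` finds local maxima above `min_height_frac` (default 5%)
of the global maximum, separated by at least `min_separation` minutes
(taller peak wins otherwise). Apexes are refined by parabolic
interpolation through the three samples around the maximum. FWHM is
measured by linear interpolation of the half-height crossings rather than
by Gaussian fitting: it is the definition used by CE data systems and is
robust to mild asymmetry. For multi-peak traces the crossing on the side
facing a neighbour is biased upward by peak overlap (at $R_s \approx 1$
the neighbour still contributes $\sim 1\%$ of height at the inner
crossing), so the first and last peaks take twice their *outer* half
width instead; no deconvolution is attempted. Areas are trapezoidal over
the valley-to-valley window clipped to 1.5 FWHM either side of the apex
(>99.98% of a Gaussian's area). Resolution follows
$R_s = 1.18\,(t_2-t_1)/(W_1+W_2)$, and is exactly invariant under common
rescaling of times and widths. The baseline is assumed flat; no
subtraction is applied by default.

For the amlodipine system the first-migrating peak is labelled (S) and
the second (R) — the (R)-enantiomer binds maltodextrin more strongly —
with the mapping configurable for other selectors.

## Synthetic campaigns

`ground_truth()` + `simulate_injection()` generate traces whose summary
statistics follow specified quadratic surfaces: the defaults are the
published amlodipine coefficient tables, injection noise SDs of 0.04
resolution units and 0.45 min (mid-range of the published per-run SD
columns, which span 0.01–0.08 and 0.02–0.80), a 1:1 S:R area ratio and
unit total area. Per injection, the second-peak time $t_2$ and the target
resolution are drawn from surface + Gaussian noise (resolution truncated
at 0, independence of the two noises assumed — the run table cannot
identify their correlation); peak width comes from a constant effective
plate number $N$ (default 50,000, typical CE efficiency) via
$W = t_2\sqrt{8\ln 2/N}$, and the first apex from exact inversion of the
resolution formula, $t_1 = t_2 - R_s \cdot 2W/1.18$. The trace is the sum
of two equal-width Gaussians sampled at 10 Hz over $[0, t_2 + 2]$ min.
Because the resolution formula is inverted exactly, round-trip accuracy
does not depend on the (undocumented in any run table) plate number.

This generator emulates the *statistical* structure a design campaign
exhibits — surfaces plus injection scatter, peak geometry consistent with
the targets — and deliberately not the physics: no electroosmotic-flow or
complexation-equilibrium model, no baseline drift, no peak tailing, no
UV spectra. Passing tests therefore demonstrate that the measurement and
modelling pipeline is self-consistent and unbiased at realistic noise
levels; they cannot certify behaviour on real instrument artifacts
(drift, tailing, spikes), which is the usual division of labour between
simulation tests and wet validation.

Verified properties (all in the test suite): measured resolution at zero
noise matches the generating value within 1% at the default 10 Hz over
the whole 27-point grid (dominant error: half-height interpolation,
$\sim 0.1\%$); a zero-noise campaign refit recovers the generating
coefficients to $10^{-4}$ at 50 Hz sampling, where discretization no
longer limits; tripling the injection SD triples the measured scatter;
and at study noise each coefficient of a 6-injection campaign refit lands
within 3 estimated SE of truth in ≥95% of 100 seeded campaigns (per
coefficient — the *joint* 3-SE coverage of seven t-distributed estimates
on 8 df is only ~91% for any correct OLS, a distinction worth remembering
when reading recovery claims).

## Quantification

`fit_calibration()` is a straight least-squares line of detector response
on concentration (five levels spanning 180–600 µg/mL in the shipped
study; peak areas by convention, heights work identically), reporting
linearity $r^2$ and the residual standard error on $n-2$ df. That
residual RMSE — not a blank SD — feeds LOD $= 3.3\,\mathrm{RMSE}/b$ and
LOQ $= 10\,\mathrm{RMSE}/b$, so LOQ/LOD is always $10/3.3$. Content is
back-calculated through the line and the dilution/volume factors from the
first-migrating (S) peak, the pharmacologically active enantiomer
(doubled on request for a racemic total); recovery is
$100\times$ measured/label, and precision is the percent RSD.

## Numerical and interface choices

* OLS through `lm.fit`'s QR; the tests additionally verify agreement
  with an explicit normal-equations solve to 10+ digits on every fixture.
* All fitting happens on coded levels; engineering units are accepted at
  every interface and coded internally, so users never hand-code runs.
* `run_pipeline()` validates its config (unknown keys, unknown factor
  names, missing columns) before any stage executes, and routes all
  randomness through one seed: a config run twice yields an identical
  report.
* Problem sizes in the tests mirror the study itself (15 runs × 6
  injections; 27-point grids; 100-campaign recovery experiments), which
  keeps the full suite around a minute of CPU.

## Known limitations

* The simulator's Gaussian, equal-width, flat-baseline peaks are an
  idealization; asymmetric or drifting real traces will stress
  `detect_peaks()` in ways the tests do not probe.
* Backward elimination is a greedy heuristic; with heavily correlated
  model columns it can drop a jointly informative pair. On near-orthogonal
  D-optimal designs this risk is small.
* The quadratic surface is trustworthy for interpolation inside the coded
  cube; mild extrapolation is permitted but flagged, and large
  extrapolation is meaningless.
* Designs with categorical factors, constrained regions, or optimality
  criteria other than D are out of scope.
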