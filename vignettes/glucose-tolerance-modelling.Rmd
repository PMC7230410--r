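---
title: "Modelling tolerance-test glucose curves as a damped linear response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tolerance-test glucose curves as a damped linear response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucodyn)
```

## The model

During a glucose tolerance test (GTT) or insulin tolerance test (ITT),
blood glucose `G` is perturbed by a bolus and then pulled back towards a
stabilized level `G0` by the net action of glucoregulatory hormones
(insulin and leptin lowering `G`, glucagon, adrenaline, cortisol and growth
hormone raising it). Linearizing the coupled glucose–hormone kinetics
around the fasted equilibrium makes the deviation `g = G - G0` satisfy a
second-order linear differential equation with constant coefficients,

$$ g'' + 2\alpha\, g' + \omega_0^2\, g = 0 , $$

with damping coefficient $\alpha$ (1/min) and squared natural frequency
$\omega_0^2$ (1/min²). The bolus itself is treated as an impulse: it is
absorbed entirely into the initial conditions $\mu = G(0)$ and
$\nu = G'(0)$, so the fitted equation is homogeneous. This reading is what
makes "optimal initial conditions" meaningful as free parameters: the five
quantities $(\alpha, \omega_0^2, G_0, \mu, \nu)$ fully determine the curve.
The hormone trajectory is never observed, so the rate constants of the
underlying two-compartment linearization are unidentifiable individually;
only their combinations $\alpha$ and $\omega_0^2$ are estimated.

The character of the solution is decided by the roots of
$r^2 + 2\alpha r + \omega_0^2 = 0$:

* **overdamped** ($\alpha^2 > \omega_0^2$): two distinct negative real
  roots, $G(t) = G_0 + C_1 e^{r_1 t} + C_2 e^{r_2 t}$ — a single excursion
  that relaxes monotonically after its extremum;
* **underdamped** ($\alpha^2 < \omega_0^2$): conjugate complex roots,
  $G(t) = G_0 + e^{-\alpha t}(A\cos\omega t + B\sin\omega t)$ with
  $\omega = \sqrt{\omega_0^2 - \alpha^2}$ — a decaying oscillation with
  basic period $T_G = 2\pi/\omega$ (reported in hours);
* **critical** (near-equal roots): evaluated with the confluent form
  $G(t) = G_0 + (C_1 + C_2 t)e^{-\alpha t}$. The regime is declared
  critical when $\alpha^2/\omega_0^2$ is within a relative $10^{-9}$ of 1;
  using the overdamped formula there would divide by $r_1 - r_2 \approx 0$
  and lose all precision to cancellation. The solution is continuous across
  the boundary (checked by a dedicated test).

The same function class describes both tests; for a GTT the excursion is
upward ($\nu > 0$, features `G_max`/`t_max`), for an ITT downward
($\nu < 0$, features `G_min`/`t_min`). All internal time units are
minutes; only the period is converted to hours.

## Fitting

`fit_glucose()` minimizes $\sum_i (G(t_i) - y_i)^2$ over a bounded box by
multi-start Levenberg–Marquardt (the `minpack.lm` engine). The defaults
encode physiologic rat glycemia: $\alpha \in (10^{-4}, 1]$ 1/min,
$\omega_0^2 \in (10^{-8}, 1]$ 1/min², $G_0 \in [1, 15]$,
$\mu \in [1, 35]$ mmol/L, $\nu \in [-5, 5]$ mmol/L/min. The start grid
crosses $\alpha \in \{0.005, 0.02, 0.05, 0.1, 0.2\}$ with
$\omega_0^2/\alpha^2 \in \{0.25, 0.5, 1, 2, 4\}$ so both root regimes are
reachable from the start set, with $\mu$ started at the first observation,
$G_0$ at the last and $\nu$ at the first finite difference; eight
additional random starts are drawn inside the box from the configured
seed, so a fit is fully deterministic given (series, config). Diagnostics
follow the usual least-squares definitions: RSS, $R^2 = 1 -
\mathrm{RSS}/\mathrm{TSS}$, and the estimated residual variance
$\mathrm{EstVar} = \mathrm{RSS}/(m - 5)$ with five free parameters — the
protocol's eight samples leave three residual degrees of freedom, which is
why at least six points are required at all.

### The acceptability gate

Not every 8-point curve belongs to this model class, so each fit carries
an `acceptable` flag. The default gate requires:

1. convergence of the best start;
2. $R^2 \ge 0.8$;
3. a residual-sign runs count inside the central 95% of the exact
   conditional runs distribution (with eight points this screen is weak —
   its discrete tails barely reach 2.5% — and it mainly catches grossly
   clustered residuals);
4. **stabilization**: for an underdamped fit, the ringing envelope
   $\sqrt{A^2 + B^2}\,e^{-\alpha H}$ remaining at the protocol horizon $H$
   must not exceed 1 mmol/L.

The fourth condition deserves explanation. With eight observations and
five parameters, a near-undamped oscillation (period ≈ 40 min,
$\alpha \to 0$) can alias through almost any two-peak pattern and reach
$R^2 \approx 0.9$ on genuinely biphasic data. Such a solution predicts
glucose oscillating by several mmol/L forever, which contradicts the
premise of a tolerance test — the subject re-establishes homeostasis — and
the very notion of a stabilized concentration $G_0$. The 1 mmol/L ceiling
is roughly three glucometer noise standard deviations; an ordinary damped
oscillatory fit passes it easily, while aliased ringing fits do not. The
gate is configurable (`fit_config(max_ring_mmol = Inf)` disables the
screen) and every rejection reason is recorded in `gate_notes`.

A constant series is degenerate: the exact fit ($\mu = G_0$, $\nu = 0$)
has zero residual but leaves $\alpha$ and $\omega_0^2$ unconstrained, so
it is returned converged yet `acceptable = FALSE` with a
non-identifiability note.

Per-animal fits are the default; `group_mean_series()` supports fitting
one pointwise-mean curve per group instead. Published group-level analyses
of this design are ambiguous between the two readings, so both are
provided and neither is asserted as canonical.

## Curve features

`extract_features()` implements the feature workflow on the fitted curve:
the extremum is the first root of $G'(t) = 0$ in (0, horizon] with the
test-appropriate curvature, located by a 0.5-min sign scan and refined by
bracketed root finding to $10^{-10}$ min; the inflection $t_I$ is the
first root of $G''(t) = 0$ after the extremum, where the decline (GTT,
$G'_I \le 0$) or recovery (ITT, $G'_I \ge 0$) is steepest. The 0.5-min
scan step is safe because physiologic parameter ranges put successive
roots tens of minutes apart. When a curve has no interior stationary point
the features are boundary-flagged ($t_{ext} = 0$, extremum $= \mu$) and a
missing inflection is reported as `NA`, never a fabricated number. For
underdamped ringing only the first admissible root is reported; later
oscillations are ignored.

The model AUC is the closed-form integral of the fitted curve over the
protocol window (240 min GTT, 180 min ITT) so it is directly comparable to
the classical trapezoidal AUC on the same window; rate features are in
mmol/L/min.

## The classical arm

`trapezoid_auc()` applies the trapezoidal rule to the raw observations.
`shapiro_normality()` screens per-group AUC samples (advisory only: the
pipeline proceeds nonparametrically regardless). `compare_groups()` runs
two-sided Mann–Whitney tests — exact when both samples have at most eight
tie-free values, otherwise the normal approximation with mid-ranks and tie
correction, appropriate since glucometer readouts are discretized to
0.1 mmol/L — with Bonferroni correction over the requested comparisons.
The default contrast set is the two within-sex, across-age pairs (young vs
adult males, young vs adult females), k = 2; sidedness and contrasts are
configurable. `classify_glycemia()` encodes the bands: severe hypoglycemia
below 2.2, hypoglycemia to 4.2, normoglycemia 4.2–5.5, hyperglycemia above
5.5 mmol/L.

## Synthetic cohorts

Raw animal data for this design are not publicly deposited, so
`generate_cohort()` simulates protocol-faithful cohorts: 4 groups
(young/adult × male/female) × 10 animals × 8 samples per test on the
canonical grids (GTT 0–240 min, ITT 0–180 min). Each animal's curve is the
group truth with per-animal jitter (lognormal factors, SD 0.1 on the log
scale, on $\alpha$ and $\omega_0^2$; Gaussian 0.2 mmol/L shifts on $G_0$
and $\mu$) plus i.i.d. Gaussian measurement noise (default SD
0.3 mmol/L), rounded to 0.1 mmol/L to mimic a consumer glucometer;
non-positive readings are redrawn. The jitter magnitudes are assumptions —
true inter-animal variability cannot be inferred from group-level
summaries — and are configurable.

`calibrated_presets()` supplies the default truths. Each is built by
closed-form inversion: with $\mu = G_0$ the overdamped response is a pure
difference of exponentials whose inflection time is exactly
$t_I = 2\ln\rho/(a(\rho - 1))$ for roots $-a$ and $-\rho a$; fixing the
root ratio $\rho = 4$ and solving for $a$ reproduces the reported
group-level inflection times exactly (GTT: 82.0, 23.1, 44.3, 19.6 min;
ITT: 122.6, 102.4, 135.7, 91.5 min for young/adult males and females).
Baselines and excursion amplitudes are set once from the reported
qualitative contrasts: adult males peak about 13% above young males in
GTT, adult females well above young females, and the young-female ITT
nadir (1.8 mmol/L) falls below the severe-hypoglycemia threshold while
males stay above it. All truths are overdamped; the oscillatory branch is
exercised by randomized property tests rather than by the presets.

The young-female GTT preset draws 70% of its animals as **biphasic
contaminants**: a sum of two admissible responses, a narrow first peak
near 15 min and a broad delayed second excursion (onset uniform on 30–45
min) peaking near 60 min and still elevated at 90 min. The mismatched
widths matter — they keep the shape outside the single damped-response
class, because one ringing mode cannot give a narrow first and a broad
second peak followed by a quiet tail. These contaminants emulate the
two-peak young-female curves that a single-response model cannot fit; they
are a test fixture, not a fitted model.

What passing tests on these cohorts do **not** show: real curves have
correlated, heteroscedastic measurement error, absorption kinetics the
impulse reading ignores, and inter-animal correlation within cages; the
generator reproduces none of these, only the curve-shape family, the
protocol grids and the glucometer discretization.

## Numerical choices and problem sizes

* Regime tolerance $10^{-9}$ (relative, on $\alpha^2/\omega_0^2$);
  confluent evaluation at criticality.
* Root scan 0.5 min, refinement tolerance $10^{-10}$ min; ties broken by
  taking the first admissible root.
* Levenberg–Marquardt with `ftol = ptol = 1e-14`, at most 200 iterations
  per start, 33 starts per fit by default.
* The validation suite integrates the ODE independently (`deSolve`), uses
  a 0.001-min dense grid for feature brute force, exact rank-test
  enumeration for samples up to n = 6, and Monte-Carlo recovery at noise
  SD 0.2 mmol/L over 100 replicates; the gate is characterized on a
  simulated cohort of ~500 animals. These sizes were chosen to keep the
  whole suite at a few minutes on a single core while leaving the
  statistical margins wide.

## Known limitations

* The hormone trajectory is neither modelled nor recoverable; $\alpha$ and
  $\omega_0^2$ absorb all compartment rate constants.
* The biphasic shape is deliberately outside the model class; the package
  flags it but does not fit two-component models.
* No standard errors or intervals are attached to fitted parameters; the
  identification is a point estimate, as in the analysis this package
  operationalizes.
* With eight points per curve the runs screen is nearly powerless; the
  effective gate is $R^2$ plus the stabilization ceiling.
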