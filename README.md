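# glucodyn

Quantitative analysis of glucose (GTT) and insulin (ITT) tolerance-test
curves in rodents. The classical readout of these tests — the trapezoidal
area under the glucose curve — often fails to separate groups whose
glucose *dynamics* differ. `glucodyn` complements it by fitting each
curve with a damped second-order linear response and reading the dynamics
off the fitted function.

## The model

The deviation of blood glucose from its stabilized level,
`g(t) = G(t) − G₀`, is modelled as

```
g'' + 2α g' + ω₀² g = 0 ,     G(0) = μ,  G'(0) = ν,
```

with damping α (1/min) and squared natural frequency ω₀² (1/min²). The
bolus enters as an impulse through the initial conditions. Depending on
the roots of the characteristic equation `r² + 2αr + ω₀² = 0` the curve
is a two-exponential excursion (overdamped), a decaying oscillation with
basic period `T_G = 2π/√(ω₀² − α²)` (underdamped), or the confluent
limiting form between them. The five parameters `(α, ω₀², G₀, μ, ν)` are
identified per curve by bounded multi-start Levenberg–Marquardt least
squares, and the fitted function yields the derived characteristics:
initial rate `G'(0)`, peak/nadir `G_max`/`G_min` and its time, the
inflection time `t_I` with the extremal rate `G'_I` (fastest decline in
GTT, fastest recovery in ITT), the stabilized level `G₀`, the oscillation
period and the model AUC.

The package also ships the conventional arm (trapezoidal AUC,
Shapiro–Wilk screening, two-sided Mann–Whitney comparisons with
Bonferroni correction, glycemic-band classification) and a synthetic
cohort generator that emulates the four study groups (young/adult ×
male/female Sprague Dawley rats, 10 animals each, 8-point protocol
grids), including biphasic two-peak contaminant curves that lie outside
the model class.

## Worked example

```r
library(glucodyn)

# simulate the four GTT groups and fit the first animal
cohort <- generate_cohort(calibrated_presets("GTT"), seed = 7)
cohort[[1]]
#> <glucose_series> young_male_gtt_01 | young_male | GTT | 8 points
#>    0   15   30   45   60   90  120  240
#>  5.1 11.0 13.1 13.0 12.6 12.0 10.4  8.3

fit <- fit_glucose(cohort[[1]])
fit
#> <glucose_fit> young_male_gtt_01 | young_male | GTT
#>   regime overdamped | rss 0.2597 | r2 0.9952 | est_var 0.08658
#>   converged TRUE | acceptable TRUE
#> Glucose response parameters:
#>   alpha     = 0.0343064 1/min
#>   omega0^2  = 0.000525802 1/min^2
#>   G0 (stab) = 7.033 mmol/L
#>   mu  G(0)  = 5.093 mmol/L
#>   nu  G'(0) = 0.6413 mmol/L/min
#>   regime    = overdamped

extract_features(fit$params, "GTT")
#> Curve features (GTT, horizon 240 min):
#>   G(0)   = 5.093 mmol/L   G'(0) = 0.6413 mmol/L/min
#>   G_max  = 13.158 mmol/L   t_max = 40.96 min
#>   G'_I   = -0.0387 mmol/L/min   t_I = 78.54 min
#>   G0     = 7.033 mmol/L   T_G = NA h   AUC = 2512.3 mmol*min/L
```

The fit is an overdamped excursion: this simulated young male peaks at
13.2 mmol/L about 41 min after the bolus and declines fastest at
t_I ≈ 79 min (close to the 82-min group truth the simulator was built
around); `T_G` is `NA` because an overdamped response does not
oscillate. The classical arm on the same cohort:

```r
aucs <- data.frame(group = vapply(cohort, `[[`, "", "group"),
                   auc   = vapply(cohort, trapezoid_auc, numeric(1)))
compare_groups(aucs)
#>        group_a      group_b statistic        p_raw   p_adjusted significant
#> 1   young_male   adult_male       100 0.0001826718 0.0003653436        TRUE
#> 2 young_female adult_female        18 0.0172574561 0.0345149122        TRUE
```

`run_pipeline(run_config(...))` binds the steps end to end (simulate or
read CSV → fit → features → AUC comparisons) and writes `fits.csv`,
`features.csv`, `classical_auc.csv`, `comparisons.json` plus provenance
and a log; identical config and seed reproduce the outputs byte for
byte.

See the vignette `vignettes/glucose-tolerance-modelling.Rmd` for the
model assumptions, the acceptability gate, and what the synthetic cohorts
do and do not emulate.

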