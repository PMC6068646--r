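# hgkrige

Geostatistical exposure assessment for residential soil mercury
contamination, and the health regressions that consume it.

Soil surveys of contaminated floodplains yield thousands of point
measurements with strong small-scale variability, while epidemiological
analyses need an exposure value — with an uncertainty — at each
participant's home. `hgkrige` implements that chain for a
mercury-contaminated area along a wastewater canal, for
biostatisticians and environmental epidemiologists:

1. **External-drift (universal) kriging** of log10 soil mercury. The
   model is `Y(s) = x(s)'β + B(s) + ε`, where the drift covariates
   `x(s)` are functions of `log10(distance to canal)` (four candidate
   drifts compared by AIC; the quadratic is the working default), `B` is
   a stationary Gaussian field with stable exponential covariance
   `C(r) = σ² exp(−(r/α)^γ)` (shape fixed at γ = 0.5) and `ε` is nugget
   noise with variance τ². Sill, nugget and range are estimated by
   Gaussian REML; prediction is the universal-kriging BLUP with a
   standard error that includes drift-estimation uncertainty.
2. **k-fold cross-validation** (default 6) of the full fit, reporting
   the Pearson correlation between predicted and measured values and
   the calibration line of predicted on measured.
3. **Mixed-model outcome regressions**: log10 urinary mercury
   (creatinine-adjusted, WHO validity range 0.3–3.0 g/L) and log10 hair
   mercury on measured or kriging-predicted soil values plus
   questionnaire covariates, with a family random intercept (`lme4`),
   Wald inference, and Bland evidence categories for communication.
4. **Berkson measurement-error correction**: kriging predictions carry
   error `x_true = x_pred + N(0, se²)`; the latent exposure integrates
   out in closed form (record-level residual variance
   `σ²_e + β²_soil·se²`), widening the soil-coefficient interval
   without moving the estimate. An MCMC route cross-checks the
   closed-form scheme.
5. **A synthetic-data generator** (`sim_config()`, `simulate_study()`)
   reproducing the statistical structure of the study design — ~3000
   topsoil samples densest near the canal, 64 families with 64 mothers
   and 107 children — so the whole pipeline runs and is testable
   without the original (non-public) data.

## Worked example

```r
library(hgkrige)

cfg   <- sim_config(seed = 42, n_soil = 500)   # study-like synthetic data
study <- simulate_study(cfg)
sdat  <- data.frame(x = study$soil$x, y = study$soil$y,
                    z = log10(study$soil$hg_mgkg))

fit <- edkrige(sdat, study$canal)              # REML + GLS drift
fit
#> External-drift kriging model (quadratic drift, gamma = 0.5, n = 500)
#> Drift coefficients:
#> (Intercept)     logdist    logdist2
#>      2.3138     -2.2594      0.3972
#> Stable exponential variogram: sill 0.1841, nugget 0.06674, range 49.23 m, shape 0.5
```

The drift coefficients recover the generating values (2.34, −2.23,
0.38): near the canal (log distance 0) the mean is ~2.3 log10 mg/kg
(≈ 200 mg/kg), falling steeply with distance. Predictions at two
unsampled locations return a mean and standard error on the log10
scale:

```r
predict(fit, data.frame(x = c(1200, 3500), y = c(650, 100)))
#>      x   y   mean    se
#> 1 1200 650 -0.666 0.361
#> 2 3500 100 -0.864 0.414
```

Cross-validation and the outcome regression on predicted exposure:

```r
edk_cv(sdat, study$canal, k = 6, seed = 42)
#> 6-fold cross-validation (n = 500)
#>   Pearson r (predicted vs measured): 0.706
#>   Calibration line: predicted = -0.310 + 0.500 * measured

fits <- run_outcome_models(study$participants, soil = study$soil,
                           model = fit, which = "urine_predicted")
wald_inference(fits$urine_predicted)   # soil term:
#>       term estimate    se ci_low ci_high p_value       evidence
#> 2 exposure   0.0809 0.112 -0.139     0.3    0.47 little_or_none
```

The correlation (0.71 here) echoes the behavior of dense survey data,
with the calibration slope < 1 showing the smoothing shrinkage of
kriging; the soil term's "little or no evidence" category is the
expected result, as the generator's default urinary soil coefficient is
0.02. The Berkson-corrected fit keeps the estimate and (at most) widens
the interval:

```r
rec <- build_exposure_records(study$participants, model = fit,
                              outcome_kind = "urine", exposure = "predicted")
berkson_lmm(rec)
#> Soil slope: corrected 0.081 [-0.139, 0.301] vs naive 0.081 [-0.139, 0.300]
```

`run_pipeline(run_config(simulate = cfg), "out/")` executes every stage
and writes one report file per stage (drift AIC table, kriging
parameters, CV summary, prediction grid, four outcome-model tables,
Berkson comparison), each stamped with the configuration hash and seed.
A thin CLI wrapper lives at `inst/scripts/hg_pipeline.R`.

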