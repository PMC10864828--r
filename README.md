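# growthrecovery

Monte-Carlo framework for a practical question in longitudinal research:
**how many measurement waves do you need before a growth model recovers
individual differences, and not just the average trend?** Researchers with
access to the first two or three waves of an in-progress cohort routinely
fit a two-wave change model or a minimally identified growth curve. This
package generates cohorts with known individual trajectories, fits the
model an analyst would fit at each number of available waves, and measures
— across many replications — how faithfully each model recovers the
group-level rate of change and the person-level growth parameters.

## The models and metrics

Individual trajectories follow a latent growth model,

```
y_ti = eta_1i + eta_2i * t + [eta_3i * t^2] + e_ti,
eta_i ~ N(alpha, Psi),   e_ti ~ N(0, sigma^2_t),
```

with time coded 0, 1, ..., T-1 and noise scaled per wave so each repeated
measure carries 50% explained variance by default. Latent factors are drawn
with *exact* sample moments (mean exactly `alpha`, covariance exactly
`Psi`), so Monte-Carlo variability comes from measurement noise and
estimation alone.

Fitted models are mean-and-covariance structures estimated by normal-theory
maximum likelihood (`growth_sem()`):

* 2 waves — the latent change score (LCS) parameterization; just
  identified, residuals fixed to zero, the change factor equals `y2 - y1`;
* 3+ waves — linear or quadratic latent curve models (LCM) with free
  per-wave residual variances;
* optionally an external covariate W whose correlations with the growth
  factors are estimated simultaneously, and full-information ML when data
  are missing.

Per-individual estimates are factor scores (regression/empirical-Bayes by
default, Bartlett optional). Recovery is quantified per replication by the
Pearson correlation between estimated and true parameters
(`pearson_recovery()`) and by a two-way agreement intraclass correlation
(`icc2_agreement()`) that also penalizes mean/scale distortion — pairing
`1:50` with `11:60` gives r = 1.00 but ICC = 0.895.

## Worked example

Fit a 3-wave linear growth model to one simulated cohort and ask how well
its slope scores recover the true individual slopes:

```r
library(growthrecovery)
s   <- sample_cohort(linear_population(), n = 200, seed = 42)
fit <- growth_sem(s, waves = 3)
summary(fit)
#> Latent curve model (degree 1), n = 200, log-likelihood = -1160.443, F_ML = 0.00416452
#>
#> Fixed effects (factor means):
#> intercept     slope
#>    3.0163    0.1245
#>
#> Random effects (factor covariance):
#>           intercept   slope
#> intercept    1.2993 -0.0833
#> slope       -0.0833  0.4086
#>
#> Residual variances:
#>     y1     y2     y3
#> 0.6650 2.0959 2.4054
#>
#> Converged: TRUE (|grad| = 1.3e-08, retries = 0)

sc <- factor_scores(fit)
pearson_recovery(sc[, "slope"], s$true_factors[, "slope"])
#> [1] 0.5613975
icc2_agreement(sc[, "slope"], s$true_factors[, "slope"])
#> [1] 0.7010105
```

The group-level picture looks fine (mean slope 0.12 against a generating
value of 0.2, within this sample's noise), but the individual slope scores
correlate only ~0.56 with the truth — three waves identify the model
without making person-level estimates trustworthy.

The full Monte-Carlo comparison across the model ladder:

```r
st <- run_study("linear_n200", n_replications = 200, seed = 7)
st
#> Recovery study 'linear_n200': 200 replications x N = 200 (seed 7)
#>   model n_converged median_fixed_linear sd_fixed_linear median_r_linear
#>  lcs_2w         200               0.188          0.1068           0.296
#>  lcm_3w         200               0.196          0.0588           0.564
#>  lcm_4w         200               0.194          0.0416           0.687
#>  lcm_5w         200               0.201          0.0352           0.766
#>  median_icc_linear
#>              0.278
#>              0.676
#>              0.787
#>              0.849
```

Read it column by column: every model recovers the fixed effect near 0.2 on
average (with sample-to-sample SD shrinking as waves accumulate), but the
median correlation between estimated and true individual slopes climbs from
~0.30 at two waves to ~0.77 at five — and the 2-wave agreement ICC (~0.28)
shows that raw change scores also badly distort the scale of individual
differences. `run_study("quadratic_n200")` and
`run_study("covariate_n200")` extend the design to quadratic growth and to
relationships with an external variable; `figure_tables()` and `plot()`
summarize distributions, and `inst/scripts/run_study.R` exposes the same
runs from a shell.

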