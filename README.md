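# diaryreact

Bayesian analysis of affective reactivity to daily stressors in
intensive-longitudinal (daily diary) data, with awareness of
age-related change (AARC) as a within- and between-person moderator.

Daily-diary studies of aging ask whether people are more reactive to
everyday stressors — higher same-day negative affect, lower vitality —
on days when they perceive their own aging more negatively. Answering
that requires machinery that psychology's standard mixed-model stack
does not provide out of the box: bounded outcomes that pile up at scale
floors/ceilings (censored likelihoods), a right-skewed negative-affect
distribution (skew-normal residuals), person-mean disaggregation of
daily predictors, and decision rules that can support a *null* as well
as an alternative (ROPE + HDI). `diaryreact` implements that pipeline
end to end for researchers working with diary data of this shape, plus
a calibrated synthetic-data generator so every estimator can be
validated by parameter recovery.

## The model

For standardized outcome `y_ij` (person *j*, day *i*):

    y*_ij = x_ij' beta + u_j + eps_ij,   u_j ~ N(0, tau^2)

* `x_ij`: intercept; baseline covariates; day (0–9), day², weekend
  (±1 coding); between-person (BP) person means and within-person (WP)
  daily deviations of AARC-gains, AARC-losses, stress severity; WP
  two-way products; the WP three-way product.
* Observed `y` is a censored realization of `y*`: days at a scale bound
  contribute CDF mass. Vitality: left-and-right censored normal.
  Negative affect: left-censored **skew normal**, mean-parameterized so
  `beta` acts on the outcome mean for any shape `alpha` (CDF via
  Owen's T).
* Priors: `beta ~ N(0, 1)`, `sigma, tau ~ half-t(3, 2.5)`,
  `alpha ~ N(0, 4)`.
* Sampling: built-in No-U-Turn sampler with compiled analytic
  gradients, non-centered intercepts, split-R-hat / ESS convergence
  gates. No external probabilistic-programming dependency.

Inference follows the dual-ROPE convention: a coefficient's 95%
highest-density interval is compared against a region of practical
equivalence of ±0.05 (main effects) and additionally ±0.025
(interactions), yielding `supports_alternative` / `supports_null` /
`undecided` verdicts plus `P_meaningful` and `P_null` posterior
proportions. Interactions are probed via reactivity slopes at ±1 SD
moderator combinations, their difference-of-differences (= 4 × the
three-way coefficient), quadratic stress curves, and PSIS-LOO elpd
model comparison.

## Worked example

```r
library(diaryreact)

# 1. simulate a diary study: 152 persons x 10 days, 83% completion,
#    outcomes generated from the package's reference coefficients
sim <- simulate_dataset(generator_config(), seed = 1)
nrow(sim$table)
#> [1] 1264

# 2. how much of daily AARC variation is within-person?
icc <- variance_components_icc(sim$table, "aarc_gains", seed = 2)
icc
#> <icc_fit> within-person variance share: 23.4%

# 3. fit the negative-affect design (left-censored skew normal)
frame <- build_model_frame(sim$table, design_spec("negative_affect"))
frame
#> <model_frame> outcome 'negative_affect' (censored_skew_normal): 1264
#>   occasions, 152 persons, 19 predictors; 97 left / 0 right censored;
#>   0 incomplete occasions dropped
fit <- fit_hierarchical(frame, chains = 2, warmup = 600, iter = 600,
                        seed = 3, check = "warn")

# 4. dual-ROPE coefficient table (excerpt)
st <- summary_table(fit)
print(st[st$role %in% c("bp", "wp"), c(1, 3:9)])
#>  predictor   est error hdi_low hdi_high below_05 within_05 above_05
#>   bp_gains -0.31  0.06   -0.44    -0.19     1.00      0.00     0.00
#>  bp_losses  0.42  0.07    0.26     0.55     0.00      0.00     1.00
#>  bp_stress  0.32  0.17    0.01     0.67     0.02      0.03     0.95
#>   wp_gains -0.09  0.03   -0.15    -0.03     0.89      0.11     0.00
#>  wp_losses  0.14  0.03    0.10     0.20     0.00      0.00     1.00
#>  wp_stress  0.19  0.01    0.17     0.22     0.00      0.00     1.00

# 5. probe the three-way interaction: reactivity slopes at +/-1 SD
slope_grid(fit)
#>   gains losses   est hdi_low hdi_high
#> 1    -1     -1 0.215   0.157    0.272
#> 2     1     -1 0.186   0.125    0.253
#> 3    -1      1 0.187   0.131    0.239
#> 4     1      1 0.186   0.127    0.242
```

Estimates are posterior means on the standardized scale; the grid
shows the reactivity slope at combinations of lower/higher WP
AARC-gains and AARC-losses. The generating values here were
`bp_gains = -0.31`, `bp_losses = 0.44`, `wp_losses = 0.13`,
`wp_stress = 0.20`: the two short chains recover them within posterior
uncertainty (the day-1-style variance share of 23.4% reflects the
single 152-person realization; at 2,000 simulated persons the
variance-components fit recovers the calibrated 25% within ±1 point —
that check is what `scripts/acceptance.R` runs).

The same pipeline runs from a shell via the thin CLI in
`inst/scripts/diaryreact-cli.R` (`simulate`, `fit`, `report`,
`compare` subcommands), and `run_simulate()` / `run_fit()` /
`run_report()` / `run_compare()` write CSV artifacts (draws,
dual-ROPE summary tables, slope grids, descriptives, elpd
comparisons) for downstream use.

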