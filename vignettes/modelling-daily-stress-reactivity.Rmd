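---
title: "Modelling daily stress reactivity with censored skew-normal multilevel models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily stress reactivity with censored skew-normal multilevel models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diaryreact)
```

## The scientific problem

Daily-diary (intensive longitudinal) studies ask the same people the same
questions every evening for a week or two. In the design this package
targets, middle-aged and older adults report, nightly: their awareness of
age-related change (AARC) — separate five-item gains and losses subscales
scored 5–25; exposure to five categories of daily stressors with a 1–5
severity rating per endorsed stressor, summed into a 0–25 daily severity
index; negative affect (six-item mean, 1–5); and subjective vitality
(six-item mean, 1–7). The substantive question is *stress reactivity*:
how strongly does same-day affect track daily stressor severity, and is
that within-person slope moderated by daily AARC-gains and AARC-losses?

Answering it requires separating stable person-level differences from
day-to-day fluctuation. Each time-varying predictor $x_{ij}$ (person $j$,
day $i$) is therefore split into a between-person component
$\mathrm{BP}_j = \bar x_{\cdot j}$ (the person mean over available days)
and a within-person component $\mathrm{WP}_{ij} = x_{ij} - \bar x_{\cdot j}$.

## The model

For outcome $y_{ij}$ (standardized long-form) the two-level model is

$$
y^*_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + u_j + \varepsilon_{ij},
\qquad u_j \sim \mathcal N(0, \tau^2),
$$

with design vector containing the intercept, baseline covariates (age,
gender, education, labor-force status, physical functioning), time
covariates (day 0–9, day², weekend), BP and WP components of AARC-gains,
AARC-losses and stress severity, the WP two-way products, and the WP
three-way product (gains × losses × stress).

Bounded diary scales pile up at their floor and ceiling, so the observed
outcome is modelled as a *censored* realization of $y^*$: values at a
bound contribute CDF mass rather than density,

$$
\log L = \sum_{\text{obs}} \log f(y_{ij}) +
\sum_{\text{at floor}} \log F(L) + \sum_{\text{at ceiling}} \log\{1 - F(U)\}.
$$

Vitality uses a censored normal (bounds 1 and 7 on the raw scale by
default — the scale's actual range; `design_spec(bounds_raw = c(1, 5))`
gives a narrower literal variant). Negative affect is right-skewed with a
hard floor at 1, so it uses a *left-censored skew normal*. We use the
mean parameterization: with shape $\alpha$, $\delta = \alpha/\sqrt{1+\alpha^2}$,

$$
\omega = \frac{\sigma}{\sqrt{1 - 2\delta^2/\pi}}, \qquad
\xi = \mu - \omega\delta\sqrt{2/\pi},
$$

so that $(\mu, \sigma)$ are the distribution's mean and SD for any
$\alpha$ and the regression acts on the outcome mean (identity link).
The CDF is $F(y) = \Phi(z) - 2\,T(z, \alpha)$ with Owen's T function.

Priors are weakly informative on the standardized scale:
$\beta_k \sim \mathcal N(0, 1)$, half-$t(\nu = 3, s = 2.5)$ truncated at
zero for $\sigma$ and $\tau$, and $\alpha \sim \mathcal N(0, 4)$.

### Preprocessing conventions

These choices pin the scale on which coefficients live and are applied
identically by the generator and the analysis:

* Continuous variables (outcomes and predictors) are standardized on the
  pooled long-form sample ($M = 0$, $SD = 1$, $n-1$ denominator).
* Disaggregation happens *after* standardization: BP and WP columns
  partition the standardized variable and are **not** re-standardized,
  so a WP column's SD is below 1 (it carries only the within-person
  variance share). Interaction products are formed from the standardized
  WP columns and likewise not re-standardized.
* Binary predictors are coded −1/+1 (male/female, non-tertiary/tertiary,
  in/out of the labor force, weekday/weekend).
* Day and day² are computed on the raw 0–9 scale, then each standardized.
* Occasions missing any model variable are listwise-deleted per
  occasion, never per person; a day with no completed survey has a
  *missing* stress index, not 0.
* Outcome values exactly at a raw censoring bound are flagged censored;
  bounds are mapped to the standardized scale with the outcome's moments.

## Inference: dual-ROPE decisions

Coefficients are summarized by the posterior mean, SD, and the 95%
highest-density interval (shortest interval containing 95% of pooled
post-warmup draws; `hdi()` searches all sorted-draw windows, which is
exact for a unimodal sample, and warns if the density dips inside the
interval). Hypothesis-style conclusions use the region of practical
equivalence: the alternative is supported when the HDI lies entirely
outside $[-w, w]$, the null when it lies entirely inside, otherwise the
verdict is undecided. Main effects use $w = 0.05$; interaction terms are
judged against both $w = 0.05$ and the laxer $w = 0.025$ because
cross-product effects are chronically underpowered. `rope_classify()`
also reports $P_{\text{meaningful}}$ (posterior mass beyond the ROPE on
the side of the posterior median — the median sign operationalizes "the
observed direction") and $P_{\text{null}}$ (mass inside). Proportions
are computed on all pooled draws and rounded only for printing.

## Probing interactions

`reactivity_slope()` evaluates, per posterior draw, the WP
stress-severity slope at chosen moderator levels:
$\beta_s + \beta_{gs} g + \beta_{ls} l + \beta_{gls} g l$. "±1 SD" is
interpreted, by default, as ±1 SD of the *WP design column* (which is
below 1 after disaggregation; `unit = "one"` uses the standardized
variable's unit instead — the convention is genuinely ambiguous in this
literature, so it is explicit and configurable). The
difference-of-differences of the four ±1 SD cells collapses
algebraically to $4 g l \beta_{gls}$ and is the effect-size summary of
the three-way interaction; `slope_differences()` returns it per draw.
`quadratic_curve()` serves the quadratic-stress variant of the design
(squared BP/WP stress, computed from the standardized columns, plus WP
AARC × squared-stress products), tracing the model-implied outcome over
a WP stress grid at ±1 SD of WP AARC-losses.

Model variants are compared on approximate leave-one-out expected log
predictive density (`elpd_loo()`): per-observation importance ratios
from the pointwise censored log-likelihood, tails stabilized by a
generalized-Pareto fit to the largest 20% of weights (Zhang–Stephens
estimator), with the shape diagnostic $\hat k$ flagged above 0.7;
standard errors use $\sqrt{n \,\mathrm{var}(\text{pointwise})}$ and
differences are oriented challenger − reference.

## Posterior computation

Sampling uses a built-in No-U-Turn sampler with analytic gradients of
the joint posterior compiled in C++. Random intercepts are non-centered
($u_j = \tau \eta_j$, $\eta_j \sim \mathcal N(0,1)$), which removes the
funnel that otherwise defeats unit-metric HMC at these sample sizes.
Warmup (default 1,000 iterations, 4 chains, 1,000 sampling iterations)
interleaves dual-averaging step-size adaptation (target acceptance 0.8)
with two diagonal mass-matrix re-estimations; seeds fix every source of
randomness, so runs are bit-reproducible. Convergence is gated on
split-$\hat R \le 1.01$ and bulk ESS $\ge 400$ (rank-normalized, Geyer
initial-monotone ESS) for every reported parameter; violations raise an
error naming the parameters, and divergent transitions after warmup are
counted and reported.

Numerical choices worth knowing:

* Owen's T is evaluated by 32-point Gauss–Legendre quadrature of its
  defining integral after reduction to $|a| \le 1$ via the standard
  reflection identity; absolute error is far below the 1e−10 the
  package's tests demand.
* Censored normal tails use `pnorm(log.p = TRUE)`; the skew-normal CDF
  is clamped away from 0/1 before logging.
* The intercept-only variance-components model
  (`variance_components_icc()`) integrates the Gaussian random
  intercepts out analytically and samples only
  $(\mu, \log\sigma, \log\tau)$ from per-person sufficient statistics,
  so the within-person variance share
  $100\,\sigma^2/(\sigma^2+\tau^2)$ is cheap even at thousands of
  persons.

## The synthetic-data generator

No raw data ship with the package, so `simulate_dataset()` generates
diary tables with the statistical structure the analysis assumes, and
its defaults *are* the reference study conditions: 152 persons × 10
days, 83% random survey completion (every person keeps ≥ 1 day), age
$\mathcal N(69.18, 5.73)$ clipped to 53–86, 66.4% women, 49.3% tertiary
educated, 85.5% outside the labor force, physical functioning
$\mathcal N(79.77, 20.46)$ on 0–100.

AARC is simulated at scale-score level (the analysis consumes scale
scores): person mean plus daily deviation, with the total SD set to the
observed day-1 scale SDs (2.62 gains, 3.23 losses) and split so the
within-person variance share is 25% (gains) and 23% (losses). Scores
are clipped to 5–25; the clip rate (~5%) is reported but clipping is
not modelled as censoring, since AARC enters as a predictor. Stressors
are five independent Bernoulli exposures per day with
$p = 0.118$ — about 0.59 events/day, inside the 0.46–0.72 band the
design calls for — and uniform severities over 1–5 (only the response
scale is pinned; uniform is the least-committal choice).

Outcomes are simulated from the two-level model itself, using the
package's reference coefficient vectors (calibrated to published
estimates from this study design) with $\tau = 0.68$, $\alpha = 4$
(negative affect) and $\tau = 0.48$, $\alpha = 0$ (vitality).
Two calibration details matter:

* **Residual SDs** ($\sigma = 0.58$ negative affect, $0.71$ vitality)
  were chosen once so the *observed* standardized outcome has
  approximately unit long-form variance — the scale on which the
  reference coefficients are defined, because the analysis standardizes
  the observed outcome. Calibrating the latent variance instead would
  inflate every recovered coefficient by the censoring-induced variance
  deficit (~7%).
* **Raw-scale placement**: negative affect is mapped to the 1–5 scale
  with mean 2.5 and SD 0.85, keeping the scale ceiling ~3 SD away (the
  model censors the floor only) while the floor yields a realistic ~7%
  left-censored days; vitality uses its observed moments (4.66, 1.36)
  with censoring at both scale bounds (~5% ceiling days).

By default the generator **moment-matches** each simulated dataset to
its generating parameters (`balance_residuals = TRUE`): residual draws
are orthogonalized against the design columns and rescaled to exact SD
$\sigma$, and the person intercept deviates are orthogonalized against
the person-level design (per-person column means) and rescaled to
exact unit SD, so $\tau$ and the coefficients hold exactly in-sample
at both levels. Single-dataset recovery at 152 × 10 otherwise carries
a dataset-realization error of the same order as the posterior SD —
WP coefficients through the residual draw, BP coefficients through
chance correlation ($\approx 1/\sqrt{152}$) between $\eta_j$ and the
person-level columns — which would make "posterior mean within 2
posterior SDs of truth" fail ~16% of the time per parameter by
construction rather than through any defect. The conditioning leaves
the marginal noise distributions essentially intact (projections of
dimension ~19 from 1,266 residuals and ~13 from 152 deviates); the
coverage-calibration tests, which need honest sampling noise, set
`balance_residuals = FALSE`.

What the generator deliberately does **not** emulate: person-level
heterogeneity in stressor exposure (so the BP stress column carries
only aggregation noise and its coefficient is weakly identified), the
negative cross-correlation between gains and losses seen in real data,
non-random dropout, serial correlation of residuals across days, and a
positive-affect process (the PA column is an uncoupled clipped-normal
filler; affect balance is derived as PA − NA at analysis time and
modelled, like negative affect, as a left-censored skew normal).
Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions — not robustness
to the ways real diary data violate them.

## Problem sizes used by the test and acceptance runs

The packaged checks use sizes chosen to exercise every code path while
staying desk-scale: variance-components recovery at 2,000 persons × 10
days; one 152 × 10 recovery dataset per outcome family fit with 2–4
chains of 600–1,000 warmup/sampling iterations; coverage calibration
over 20 replicates at 30 persons × 5 days with a single chain; and
analytic ROPE/HDI/elpd checks on $10^5$ draws.

## Known limitations

* One sampler specialization: the compiled NUTS serves the two
  implemented families only; random slopes and other links are out of
  scope.
* The HDI is a single shortest interval; genuinely multimodal
  posteriors trigger a warning rather than a disjoint interval.
* PSIS-LOO inherits the usual caveat that observations with
  $\hat k > 0.7$ need refitting, which the package flags but does not
  automate.
* The affect-balance family choice (left-censored skew normal at −4) is
  a package convention; the source analyses report only that balance
  results mirrored negative affect.
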