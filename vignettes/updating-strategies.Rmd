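---
title: "Extending a risk model with a new marker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending a risk model with a new marker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predext)
```

## The problem

A logistic-regression risk model — here the running example is a prostate
biopsy risk calculator built on PSA, prostate volume and digital rectal exam
(DRE) — has been developed on a large cohort. A promising new marker (a
continuous blood index in the running example) becomes available, but only
in a separate, often much smaller, dataset. How should the existing model be
extended with the marker, given that refitting everything on a small marker
set invites overfitting, while refitting nothing wastes the marker?

The existing model supplies a linear predictor for patient $x$:

$$\mathrm{lp}_0 = \alpha + \textstyle\sum_{i=1}^{p} \beta_i x_i .$$

`predext` implements the competing extension strategies, the performance
measures used to compare them, and a simulation framework with a synthetic
population so all comparisons can be reproduced from code alone.

## The strategies

**Model revision with extension** (`revise_with_extension()`) refits all
coefficients plus the marker on the marker set:
$\mathrm{lp}_1 = \hat\alpha + \sum \hat\beta_i x_i + \hat\beta_{p+1} m$
($p + 2$ estimated parameters).

**Recalibration** (`recalibrate()`) fits only a new intercept and an overall
slope on the frozen $\mathrm{lp}_0$:
$\mathrm{lp}_2 = \hat\alpha + \hat\beta_{\mathrm{overall}} \mathrm{lp}_0$
(2 parameters; no marker).

**Model revision with shrinkage** (`revise_with_shrinkage()`) blends the two,
$\mathrm{lp}_3 = \hat c\,\mathrm{lp}_1 + (1-\hat c)\,\mathrm{lp}_2$, with the
heuristic shrinkage factor
$\hat c = \max(\chi^2 - \mathrm{df}, 0)/\chi^2$, where $\chi^2$ is the
$-2\log L$ difference between the recalibrated and the revised fit and
$\mathrm{df}$ the difference in their parameter counts. Since
$\mathrm{lp}_2$ carries no marker term, the effective marker coefficient is
$\hat c\,\hat\beta_{p+1}$ — shrunk toward zero when the likelihood gain of
full revision is small.

**Recalibration with extension** (`recalibrate_with_extension()`) fits
$\mathrm{lp}_4 = \hat\alpha + \hat\beta_{\mathrm{overall}} \mathrm{lp}_0 +
\hat\beta_{p+1} m$ (3 parameters for one marker).

**Conditional likelihood ratio (CLR) updating** (`fit_clr()`,
`fit_clr_simple()`) leaves the existing model untouched and updates its
*predictions* by Bayes' rule. With the marker modelled as conditionally
normal given the predictors in each outcome group,

$$\mathrm{LR} =
  \frac{\phi\!\left(m;\, \mu_{\text{case}}(x),\, \sigma_{\text{case}}\right)}
       {\phi\!\left(m;\, \mu_{\text{control}}(x),\, \sigma_{\text{control}}\right)},
\qquad
\text{posterior odds} = e^{\mathrm{lp}_0} \times \mathrm{LR} .$$

The full variant fits one ordinary-least-squares marker regression per
outcome group ($2(p+1)$ mean coefficients + 2 residual SDs); the simple
variant fits a single regression with an outcome indicator ($p+2$
coefficients + 1 shared SD), so the case and control means differ only by a
constant.

**Imputation** (`impute_marker()` + `fit_pooled()`) stacks the development
set (marker systematically missing) with the marker set, multiply imputes
the missing marker 10 times, fits the extended logistic model per completed
dataset, and pools coefficients by their mean (Rubin's rules for point
estimates). It is the only strategy that needs the development data, and in
exchange it fits its $p + 2$ parameters on the largest possible sample.

`parameter_count()` tabulates the accounting; at the case study's
$p = 3, m = 1$ it gives 5 (revision, shrinkage, imputation), 3
(recalibration with extension), 10 (full CLR) and 6 (simple CLR).

## Performance measures

Discrimination is the concordance statistic (`concordance_statistic()`):
the probability that a random event outranks a random non-event, ties
counted ½, computed by the midrank Wilcoxon identity in $O(n \log n)$ —
exactly equal to the all-pairs definition. Calibration is the calibration
slope (`calibration_slope()`): the ML slope of outcome on the model's
log-odds in validation data. A slope below 1 is the overfitting signature —
predictions more extreme than the outcomes warrant. For the CLR strategies
the log-odds is the posterior log-odds $\mathrm{lp}_0 + \log \mathrm{LR}$,
which keeps the slope comparable across strategies.

## The synthetic population

The original patient data are not available, so the generator
(`population_config()`, `generate_dataset()`) states a parametric world
anchored to the published cohort summaries:

| quantity | default | anchor |
|---|---|---|
| PSA | log-normal, median 3.1 ng/ml, sdlog 0.19 | development-cohort median (IQR 2.8–3.6) |
| volume category | 20.4 / 47.8 / 31.8 % | development-cohort shares |
| abnormal DRE | 35.4 % | development-cohort share |
| outcome prevalence | 24 % | development-cohort biopsy-positive rate |
| marker | conditionally normal given covariates and/or outcome | marginal quartiles ≈ 34/45/61 in marker cohorts |

Two truth models are provided, mirroring the two model families so each is
evaluated under a generator that favours it:

* **logistic truth** (`default_logistic_config()`): marker drawn given
  covariates, outcome drawn from the full logistic model
  (covariates + marker);
* **CLR truth** (`default_clr_config()`): outcome drawn from the prior
  (no-marker) model, marker drawn from the realized group's conditional
  normal — exactly the data-generating process the CLR updater assumes.

Outcomes use the uniform-threshold rule $Y_i = \mathbf{1}\{p_i \ge u_i\}$,
$u_i \sim U(0,1)$.

The published truth coefficients live in supplementary material that is not
part of the main text, so the defaults here were derived once, by numeric
calibration (`scripts/calibrate_truth.R`), to hit the stated anchors: a
prior-model c-statistic of ≈ 0.69 and a full-truth c-statistic of ≈ 0.73–0.74
in large validation samples, prevalence 24 %. The achieved values
(n = 400,000 checks) are prevalence 0.236/0.239, c = 0.690 → 0.734
(logistic truth) and 0.690 → 0.733 (CLR truth), marker quartiles 34/44/56.
These values are frozen; they are the stated world of every test, not
tuning knobs. Exact numeric reproduction of the publication's figures is
*not* claimed — the original study resampled real patients — only the
qualitative orderings.

What the generator does **not** emulate: site heterogeneity (the real marker
cohorts differ in PSA levels and prevalence), dependence among PSA, volume
and DRE (independent by default), skewness of the marker's marginal within
outcome groups (conditionally normal by construction, as the CLR truth
requires), and predictor missingness. A green simulation test therefore
establishes the comparative behaviour of the strategies under a homogeneous
population, not their performance under dataset shift.

## Simulation design

`scenario_config()` + `run_scenario()` reproduce the experimental design:
per replicate, a development set (marker dropped) of size $n_{dev}$, a
marker set of size $n_{marker}$, the prior model fitted on the development
set, every strategy applied, and both measures evaluated on a fresh
independent test set (default 100,000). The three headline scenarios are
(500, 100), (100, 500) and (500, 500). Default replicates: 500 (the figure
captions' count; the methods text mentions 1,000 — configurable).

Numerical/design choices, made once:

* **Fitting.** Damped Newton/IRLS, relative $-2\log L$ tolerance $10^{-8}$,
  100 iterations max, step-halving. *No penalization anywhere*: exposing
  small-sample overfitting is the point, so a ridge fallback would bias the
  comparison. Separation (perfect fit at finite coefficients, or diverging
  coefficients) flags the fit `converged = FALSE`; the simulation excludes
  and counts such replicates per strategy instead of aborting.
* **df in $\hat c$.** The parameter-count difference of the two nested fits
  ($p$ for the encoded design). An override argument exists because another
  published accounting ($p - 1$) is in circulation; the count difference is
  self-consistent and auditable.
* **CLR residual SDs.** Unbiased OLS form, denominator $n - q$; the source
  texts do not state a denominator. No small-sample pooling correction for
  the simple variant's shared SD — plain OLS.
* **Imputation engine.** One variable is ever missing, so chained equations
  reduce to a single Bayesian linear-regression imputation:
  $\sigma^{*2} \sim \mathrm{SSE}/\chi^2_{n-q}$,
  $\beta^* \sim N(\hat\beta, \sigma^{*2}(Z'Z)^{-1})$, then draws with
  residual noise (proper imputation). The outcome is a covariate of the
  imputation model — omitting it would bias the marker–outcome association
  in the completed data.
* **Probability clamping.** Likelihood evaluation clamps probabilities at
  $10^{-12}$ from each boundary; CLR posterior arithmetic is done entirely on
  the log-odds scale, so extreme markers cannot overflow.
* **Replicate seeding.** A root seed draws one 31-bit sub-seed per
  replicate; each replicate re-seeds from its own value, making replicates
  independent and individually reproducible.
* **Fresh test set per replicate.** The design text permits one shared
  validation sample; fresh draws avoid cross-replicate correlation and leave
  every expectation unchanged.
* **Categorical encoding.** Reference-cell dummy coding, first level as
  reference. The encoded width $p$ (4 for the default schema: PSA + two
  volume dummies + DRE) is what all parameter-count bookkeeping uses, while
  the case-study table's $p = 3$ counts clinical variables; both views are
  supported because `parameter_count()` takes $p$ as an argument.

## Worked example

```{r example, eval = FALSE}
cfg   <- default_logistic_config()
dev   <- drop_marker(generate_dataset(cfg, 500, seed = 1))
mk    <- generate_dataset(cfg, 100, seed = 2)
test  <- generate_dataset(cfg, 100000, seed = 3)

prior <- fit_logistic(dev)
strategies <- list(
  original   = prior,
  revision   = revise_with_extension(mk),
  shrinkage  = revise_with_shrinkage(prior, mk),
  recal_ext  = recalibrate_with_extension(prior, mk),
  clr        = fit_clr(prior, mk),
  clr_simple = fit_clr_simple(prior, mk),
  imputation = fit_pooled(impute_marker(dev, mk, seed = 4))
)
sapply(strategies, function(m) unlist(evaluate_performance(m, test)[1:2]))
```

A full replicated comparison is one call:
`run_scenario(scenario_config(500, 100, n_replicates = 500, seed = 1))`.

## Known limitations

* One homogeneous population: the development and marker sets share the
  truth. Heterogeneity between populations — where CLR-style updating is
  known to inherit the prior's miscalibration — is expressible by building
  two configs but is not exercised by any shipped test.
* Single continuous marker. Multi-marker fitting, stepwise marker selection
  and summary scores are out of scope (`parameter_count()` alone handles
  general $m$).
* Point-estimate pooling only; Rubin's total-variance formula is not
  implemented (nothing downstream consumes pooled standard errors).
* No decision-analytic measures (net benefit, NRI, relative utility).
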