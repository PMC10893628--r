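# parahaz

Parametric additive hazard regression for right-censored time-to-event
data.

## The problem

Proportional hazards regression summarizes covariate effects as hazard
ratios, which are frequently criticized as hard to interpret (they are
not relative risks, they are non-collapsible, and they carry built-in
selection effects over time). Additive hazard models avoid these issues:
a covariate shifts the event *rate* by an additive amount,

```
h_x(t) = h_0(t) + x'beta,
```

so `beta` reads directly in absolute terms — with time in years,
`beta = 0.8` means an extra 80 events per 100 person-years in the exposed
group. Classical additive hazard models (Aalen; Lin–Ying) leave the
baseline non- or semi-parametric. `parahaz` instead makes the baseline
hazard `h_0` fully parametric, which gives closed-form survival and
density functions,

```
S_x(t) = S_0(t) / exp(t x'beta),
f_x(t) = (f_0(t) + x'beta S_0(t)) / exp(t x'beta),
```

a plain maximum-likelihood fit (events contribute `log f`, censored
observations `log S`), and a *relative survival* interpretation

```
S_x(t) / S_0(t) = exp(-t x'beta)
```

that does not depend on the chosen baseline family at all.

The package is aimed at biostatisticians and epidemiologists who want
absolute-scale effect estimates from cohort data, and at methodologists
who want a reproducible Monte-Carlo harness for comparing additive-hazard
estimators.

## What is in the package

- Six baseline families — exponential, Weibull, gamma, Gompertz,
  log-normal, log-logistic — with closed-form survival, density, hazard,
  cdf, quantile, mean and median (`ah_baseline()`, `baseline_*()`).
- The model equations and censoring-aware log-likelihood (`ah_model()`,
  `ah_hazard()`, `ah_survival()`, `ah_density()`, `relative_survival()`,
  `ah_loglik()`).
- Maximum-likelihood fitting with Wald intervals, AIC/BIC, delta-method
  intervals for the baseline mean/median, and multi-family comparison
  tables ranked by BIC (`ah_fit()`, `ah_compare()`,
  `baseline_summaries()`, `relative_survival_curve()`).
- The closed-form Lin–Ying semi-parametric additive hazard estimator with
  sandwich variance, as comparator (`lin_ying()`).
- A survival-data simulator: inverse-transform sampling from the additive
  hazard cdf for a balanced binary covariate, Bernoulli event status and
  uniform down-scaling censoring (`sim_design()`, `sim_dataset()`,
  `sample_event_time()`, `apply_censoring()`).
- A simulation-study harness over a 24-setting factorial grid computing
  bias (mean and median), MSE, empirical coverage and convergence counts
  for three estimators (`sim_settings()`, `run_setting()`,
  `run_sim_study()`, `summarize_metrics()`).
- Delimited-file I/O, Kaplan–Meier overlays and a command-line interface
  (`read_survival_data()`, `write_survival_data()`, `kaplan_meier()`,
  `inst/cli/parahaz` with `fit` / `compare` / `simulate` / `simstudy`
  subcommands).

See the vignette `vignettes/parametric-additive-hazards.Rmd` for the
methods, parameterizations and numerical choices.

## Worked example

```r
library(parahaz)
set.seed(2026)

# a two-arm cohort of 400 subjects, Weibull baseline (shape 0.86,
# scale 1.77 years), additive effect 0.8 per person-year, 20% censoring
d <- sim_dataset(sim_design("weibull", c(0.86, 1.77), beta = 0.8,
                            n = 400, event_fraction = 0.8))
fit <- ah_fit(d, "weibull")
fit
#> Parametric additive hazard model (weibull baseline)
#> N = 400 (339 events), logLik = -435.88, AIC = 877.8, BIC = 889.7, converged: TRUE
#> Estimates with 95% Wald confidence intervals:
#>   theta.shape        0.8471  [0.7613; 0.9425]
#>   theta.scale        2.2052  [1.8370; 2.6472]
#>   beta.x             0.7220  [0.5240; 0.9201]
#>   baseline mean:   2.4043 [1.9576; 2.8511]
#>   baseline median: 1.4307 [1.1524; 1.7089]
```

The fitted `beta.x` of 0.72 [0.52; 0.92] estimates the additive excess
hazard of the exposed group: about 72 extra events per 100 person-years,
with the generating value 0.8 inside the interval. (The visible upward
drift of the baseline scale is a property of the uniform down-scaling
censoring scheme, discussed in the vignette.) The baseline mean and
median are delta-method summaries of the fitted Weibull.

Relative survival of the exposed group — identical under every baseline
family — and a BIC comparison across candidate baselines:

```r
relative_survival_curve(fit, t = c(1, 2, 5))
#>   time estimate  lower  upper
#> 1    1   0.4858 0.3985 0.5922
#> 2    2   0.2360 0.1588 0.3507
#> 3    5   0.0271 0.0100 0.0728

ah_compare(d, families = c("weibull", "loglogistic", "lognormal"))
#>  Distribution              beta        Baseline Mean   Baseline Median No. params   BIC
#>       weibull 0.72 [0.52; 0.92]    2.40 [1.96; 2.85] 1.43 [1.15; 1.71]          2 889.7
#>   loglogistic 0.73 [0.53; 0.93] 10.37 [-0.54; 21.28] 1.32 [1.04; 1.60]          2 914.3
#>     lognormal 0.71 [0.51; 0.91]    4.46 [2.73; 6.18] 1.21 [0.93; 1.49]          2 926.0
```

The generating Weibull family attains the smallest BIC; all three
families agree closely on `beta`, while the baseline location summaries
differ — exactly the behaviour that motivates reporting both.

The same analyses are available from the shell:

```sh
inst/cli/parahaz simulate --family weibull --theta 0.86,1.77 --beta 0.8 \
    --n 400 --event-fraction 0.8 --seed 2026 --out cohort.csv
inst/cli/parahaz fit --data cohort.csv --family weibull
inst/cli/parahaz simstudy --settings WBAH_0.8_200_0.8 --replicates 100 \
    --seed 1 --out results.csv
```

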