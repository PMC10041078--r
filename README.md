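# tagcor

Correlated survival–recovery random effects in Brownie tag-recovery models,
with a built-in known-fate population simulator and a simulation-based power
analysis for detecting additive harvest mortality.

## The problem

Tag-recovery (band-recovery) studies release marked animals each year and
re-encounter some of them when hunters recover and report their tags.  The
Brownie model summarises such data in an *m-array* — rows are release
cohorts, columns are recovery years, plus a never-recovered column — and
models each cohort as a multinomial whose cell probabilities combine annual
survival `S_y` and recovery `f_y` (the joint probability of being shot,
retrieved, and reported).  For two age classes (hatch-year juveniles, HY, and
after-hatch-year adults, AHY), a juvenile released in year `i` is recovered
directly with probability `f_HY,i`, survives its first winter with `S_HY,i`,
and thereafter lives at adult rates, so

    alpha[i,i] = f_HY,i
    alpha[i,j] = S_HY,i * prod(S_AHY,k; k = i+1..j-1) * f_AHY,j   (j > i)
    beta[i,i]  = f_AHY,i
    beta[i,j]  = f_AHY,j * prod(S_AHY,k; k = i..j-1)              (j > i)

Annual rates are modelled hierarchically on the logit scale,
`logit(S_y) = mu_S + eps_S,y`, `logit(f_y) = mu_f + eps_f,y`, with the pair
`(eps_S,y, eps_f,y)` drawn from a bivariate normal whose correlation `rho` is
the quantity of scientific interest: strongly negative `rho` is read as
evidence that harvest mortality is *additive* to natural mortality
(conventional bins at −0.7 / −0.5 / −0.3 / 0.3), while `rho` near 0 suggests
*compensatory* harvest.  Three priors for the covariance structure are
implemented — `Wishart(3, I)` on the precision matrix, `Uniform(0,5)` SDs
with a flat correlation prior, and `Gamma(1.001, 0.001)` precision diagonals
with a flat precision-correlation prior — because the posterior for `rho`
turns out to depend heavily on this choice.

The package is aimed at analysts of harvested bird and fish populations who
want to (a) fit these models without hand-writing BUGS/JAGS code, and
(b) *check before trusting*: simulate a population with known correlation,
subsample it at the monitoring intensity of their own study, and measure
whether their prior/sample-size combination can recover the truth at all.

## What's inside

* `marray_pair()`, `build_marray()`, `known_fate_summary()`,
  `read_marray_csv()` — m-array construction, validation, I/O, and the
  *known-fate years* sample-size metric (a recovery at lag L contributes L
  years; direct recoveries contribute none).
* `fit_brownie(data, prior, control)` — posterior sampling via a
  purpose-built adaptive Metropolis-within-Gibbs sampler in C++ (conjugate
  Gibbs block for the Wishart prior), returning a classed fit with `print`,
  `summary`, `coef`, `plot`, `as.matrix`/`as.data.frame`, `rhat` and
  `annual_rates` methods.
* `sim_hyperparams()`, `draw_annual_rates()`, `simulate_population()`,
  `realized_rates()`, `realized_correlation()`, `beta_slope()` — the
  known-fate population simulator (trinomial yearly fates: recovered /
  die unrecovered / survive).
* `monitoring_scenario()`, `sample_realization()`, `summarize_realizations()`
  — monitoring designs (modest 250/800 per year, episodic, intermediate
  2,000, intensive 10,000) and without-replacement subsampling of the
  simulated population.
* `run_power_analysis()`, `power_table()`, `bin_proportions()`,
  `compensatory_rate()` — the full scenarios × realizations × priors grid
  with additivity-bin summaries.
* `seber_r()`, `seber_scenario()`, `seber_slopes()` — a closed-form
  demonstration of why the Seber `r = f/(1−S)` parameterisation can reverse
  the apparent survival–harvest relationship.

## Worked example

```r
library(tagcor)

set.seed(1)
hyper <- sim_hyperparams()            # 36 years, juvenile S 0.574 / f 0.061,
                                      # adult S 0.571 / f 0.032, rho = -0.8
rates <- draw_annual_rates(hyper)
pop <- simulate_population(rates, n_HY = 250000, n_AHY = 400000)
realized_correlation(pop, "HY")
#> [1] -0.7283562

m <- sample_realization(pop, monitoring_scenario("intensive"))
known_fate_summary(m, "HY")
#> HY: 360000 releases, 21617 direct + 15736 indirect recoveries
#> known-fate years: 35610 total, 989.2 per year, 0.099 per release

fit <- fit_brownie(m, prior = "uniform",
                   control = brownie_control("desk", seed = 2))
print(fit)
#> Hierarchical Brownie tag-recovery model fit
#>   prior: uniform | 36 years | releases HY 360000, AHY 360000
#>   4000 retained draws (4 chains)
#>   mean_S_HY     0.598 ( 0.579,  0.617)  Rhat 1.004
#>   mean_f_HY     0.059 ( 0.054,  0.063)  Rhat 1.002
#>   mean_S_AHY    0.573 ( 0.558,  0.587)  Rhat 1.000
#>   mean_f_AHY    0.032 ( 0.030,  0.035)  Rhat 0.999
#>   rho_HY       -0.641 (-0.861, -0.288)  Rhat 1.002
#>   rho_AHY      -0.708 (-0.870, -0.432)  Rhat 0.999
```

This seed's 36-year draw happened to realize a correlation of −0.73 (single
draws at n = 36 scatter widely around the −0.8 target), and the posterior
medians track it; both credible intervals exclude most of the compensatory
range.  With `prior = "wishart"` the same data give medians around −0.4 —
the attenuation that motivates the power analysis.  With a modest design
(250 juveniles / 800 adults per year) credible intervals overlap zero and
the study cannot distinguish additive from compensatory harvest.

`summarize_realizations(sample_realizations(pop, scenario, n = 50))`
reproduces the sample-size tables (means and SDs of known-fate years,
direct and indirect recoveries across realizations), and

```r
pw <- run_power_analysis(pop, scenarios = list("modest", "intensive"),
                         priors = c("wishart", "uniform", "gamma"),
                         n_realizations = 50, seed = 1)
power_table(pw)
```

produces the median-correlation and additivity-bin table per (scenario,
prior, age class), plus the rate at which each design would wrongly conclude
compensatory harvest.

## Acceptance script

`scripts/acceptance.R` recomputes the simulation-study reference quantities
from scratch with the installed package: it draws the 36-year reference rate
trajectory at the published hyperparameters, simulates the full known-fate
population (250,000 juveniles and 400,000 adults released per year),
computes the realized juvenile survival–recovery correlation and the
natural-scale survival-on-recovery slope, then samples 50 intensive-scenario
realizations and summarises their direct recoveries and known-fate years.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/power-analysis-methods.Rmd` documents the model, the fate
process behind the simulator, the sampler design, every tunable default, and
the known limitations of the reduced-scale checks.
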