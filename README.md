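# odbinom

Simulation and estimation tools for **overdispersed Binomial mixed models**
of proportion data (e.g., eggs hatched out of a clutch across several
populations). The package exists to answer a practical modelling question:
when proportion data show more variation than a Binomial mixed model
allows, should you absorb it with an **observation-level random effect
(OLRE)** or model it explicitly with a **Beta-Binomial** distribution — and
what goes wrong if you pick the remedy that does not match the process that
generated the overdispersion?

## The models

For individual *i* in population *j(i)*, hatched count *h&#8342;* out of
clutch *c&#8342;*:

```
h_i  ~ Binomial(c_i, p_i)
logit(p_i) = alpha_j(i) + beta_prey * Prey_i + beta_bodysize * Bodysize_i
alpha_j ~ Normal(mu_pop, sigma_pop^2)
```

* **OLRE**: add `eps_i ~ Normal(0, sigma_eps^2)` to the linear predictor of
  every row.
* **Beta-Binomial**: draw the Binomial probability from
  `Beta(p_i/phi, (1-p_i)/phi)`; the intraclass correlation between trials is
  `phi/(1+phi)` and the variance is inflated by `1 + (c_i-1) phi/(1+phi)`.

The package simulates data under *both* overdispersion mechanisms
(`simulate_dataset()`), fits all three model families by exact marginal
maximum likelihood with Gauss–Hermite quadrature (`fit_ml()`), measures
overdispersion with the Pearson dispersion statistic and a parametric
bootstrap (`pearson_dispersion()`, `bootstrap_dispersion_ci()`), fits the
Bayesian Beta-Binomial hierarchical model by adaptive
Metropolis-within-Gibbs with the Gelman–Rubin diagnostic
(`sample_posterior()`, `gelman_rubin()`), and runs replicated
parameter-recovery studies over scenario grids (`run_replicates()`,
`run_full_study()`).

## Worked example

```r
library(odbinom)

# strong Beta-Binomial overdispersion, 10 populations x 20 individuals
cfg <- scenario_config("beta_binomial", phi = 2,
                       n_populations = 10, n_per_population = 20,
                       clutch_size = 5)
d <- simulate_dataset(cfg, seed = 42)

fit_ml(d, model_spec("beta_binomial"))
#> Beta-Binomial mixed model fit by marginal ML (200 obs)
#>   mu_pop = -0.5452  beta_prey = 0.5404  beta_bodysize = -0.0081
#>   sigma_pop = 0.3072  phi = 2.0279
#>   logLik = -279.1535  converged = TRUE

fit_ml(d, model_spec("binomial", olre = TRUE))
#> Binomial + OLRE mixed model fit by marginal ML (200 obs)
#>   mu_pop = -1.4881  beta_prey = 1.4607  beta_bodysize = -0.0279
#>   sigma_pop = 0.5812  sigma_eps = 4.9085
#>   logLik = -276.2350  converged = TRUE

pearson_dispersion(d, fit_ml(d, model_spec("binomial")))$point
#> [1] 3.509757
```

The generating truth here is `beta_prey = 0.6`. The Beta-Binomial model
(which matches the generating mechanism) recovers it — and recovers `phi`
— while the OLRE model inflates the prey slope to 1.46 on this dataset:
the characteristic failure mode when an OLRE is asked to absorb
Beta-Binomial mixing. The base Binomial fit is heavily overdispersed
(dispersion 3.5 on 196 residual df). Replicated versions of exactly this
comparison, across overdispersion levels, numbers of populations and clutch
sizes, are what `run_full_study(default_study_design())` produces.

A command-line front end over the same functions (subcommands `simulate`,
`fit`, `dispersion`, `run-study`) is installed at
`inst/cli/odbinom-cli.R`.

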