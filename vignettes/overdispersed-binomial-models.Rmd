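---
title: "Methods: overdispersed Binomial mixed models in odbinom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overdispersed Binomial mixed models in odbinom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Proportion data — eggs hatched out of a clutch, infected animals out of a
group — are routinely modelled with Binomial mixed models. Real biological
data are very often *overdispersed*: the observed counts vary more than a
Binomial model predicts, because of unmeasured covariates, aggregation, or
genuine heterogeneity between observational units. Ignoring overdispersion
biases both effect sizes and their standard errors. Two standard remedies
exist, and they are not equivalent:

* an **observation-level random effect (OLRE)** — each row gets its own
  Normal intercept on the logit scale, which "soaks up" extra-Binomial
  variation;
* a **Beta-Binomial model** — the Binomial success probability of each row
  is drawn from a Beta distribution, giving a compound distribution with an
  explicit dispersion parameter.

`odbinom` provides both models (plus the plain Binomial baseline), a
simulator that generates overdispersion by either mechanism, a dispersion
diagnostic, and a replicated-study harness, so that the behaviour of each
model on each kind of data can be quantified by parameter recovery.

## Models

For individual $i$ in population $j(i)$, with clutch size $c_i$ and hatched
count $h_i$:

$$h_i \sim \mathrm{Binomial}(c_i, p_i), \qquad
\mathrm{logit}(p_i) = \alpha_{j(i)} + \beta_{prey}\,Prey_i +
\beta_{bodysize}\,Bodysize_i,$$
$$\alpha_j \sim \mathrm{Normal}(\mu_{pop}, \sigma_{pop}^2).$$

The OLRE variant adds $\varepsilon_i \sim \mathrm{Normal}(0,
\sigma_\varepsilon^2)$ to the linear predictor of each row. The
Beta-Binomial variant instead draws the Binomial probability from
$\mathrm{Beta}(a_i, b_i)$ with $a_i = p_i/\phi$, $b_i = (1-p_i)/\phi$, so
that $\mathbb{E}[h_i] = c_i p_i$ and the intraclass correlation between
trials of one row is $\rho = \phi/(1+\phi)$, inflating the variance by
$1 + (c_i - 1)\rho$. Larger $\phi$ (or $\sigma_\varepsilon$) means stronger
overdispersion; both are accepted at 0, where each model collapses to the
plain Binomial.

## The data generator

`simulate_dataset()` emulates a multi-population clutch study with a fixed
truth of $\mu_{pop} = -1$ (baseline hatch rate $\approx 0.27$),
$\sigma_{pop} = 0.5$, $\beta_{prey} = 0.6$ and $\beta_{bodysize} = -0.01$.
The default design ladders are: overdispersion $\phi \in \{0.1, 1, 2\}$ or
$\sigma_\varepsilon \in \{0.1, 1.5, 3\}$ at 10 populations of 20; random
effect levels $J \in \{3, 5, 20\}$ at strong overdispersion; clutch size
$\in \{2, 4, 10\}$; and a total-sample-size control (3 populations of 67).

Covariate laws are a genuine design choice: prey intake is standard normal
and body size is uniform on $[-10, 10]$, chosen once so that the body-size
effect spans roughly 0.2 logits — about a 4 percentage-point difference in
hatch rate between the smallest and largest individuals — which makes
$\beta_{bodysize}$ a deliberately weak signal whose *sign* is easy to get
wrong under overdispersion. Clutch size is a scenario constant, designs are
perfectly balanced, and covariates are redrawn for every replicate dataset.
Real datasets are of course unbalanced, contain covariate measurement error
and rarely have Gaussian/uniform covariates; passing recovery tests here
demonstrates correctness of the estimators under the stated generative
models, not robustness to those complications.

## Maximum-likelihood fitting

`fit_ml()` maximizes the exact marginal likelihood, integrating the
population intercept with non-adaptive Gauss–Hermite quadrature (default
order 20). For the OLRE model each row's effect is integrated by a nested
inner quadrature (default order 15): given the population intercept the row
effects are independent, so the per-population integrand factors over rows.
The Beta-Binomial row term is the compound pmf evaluated through log-gamma
(shapes can be far below 1 at $\phi = 2$, where direct Beta-function
evaluation underflows). A dense-trapezoid brute-force integrator
(`loglik_bruteforce()`, $\pm 8$ SD, $\ge 2000$ points per latent dimension)
serves as the accuracy oracle in the tests: the single-latent-dimension
families agree with it to $10^{-6}$ from order 15, while the nested OLRE
integral reaches $10^{-6}$ around order 40. The fitting defaults (20/15)
leave a likelihood error on the order of $10^{-4}$, which is negligible
against the replicate-to-replicate scatter that all reported summaries are
built from; orders are configurable through `glmm_control()`.

Numerical choices: optimization is on the unconstrained scale
($\log \sigma$, $\log \phi$) with `nlminb`; fitted probabilities are clamped
to $[10^{-12}, 1 - 10^{-12}]$; $\phi < 10^{-8}$ switches to the Binomial
limit directly because lgamma differences lose precision there; SD estimates
below $10^{-4}$ are reported as exactly 0 (boundary fits are common at
$J = 3$); starting values come from a plain GLM, with up to 3 jittered
restarts, and a dispersion model additionally falls back to the fitted
Binomial submodel's optimum with near-zero dispersion, which guarantees the
nesting inequality between the OLRE model and its Binomial submodel. All
failures are recorded in the returned object (`converged = FALSE`), never
raised, so the study harness can report failure rates; summaries are over
converged fits only, with counts reported.

## Dispersion diagnostic

`pearson_dispersion()` is the ratio of the sum of squared Pearson residuals
to residual degrees of freedom ($n_{obs}$ minus fixed-effect and variance
parameters); values above 1 indicate overdispersion. Fitted probabilities
are *conditional*: fixed effects plus the posterior mode of each population
intercept at the ML parameters and, for OLRE fits, the posterior mode of
each observation effect — the convention of the standard GLMM dispersion
checks. Including the predicted OLRE is essential: it is precisely how the
OLRE absorbs extra-Binomial variation, and it is what drives the
diagnostic back toward (often below) 1 after an OLRE is added to an
overdispersed model. `bootstrap_dispersion_ci()` is a parametric bootstrap
*under the fitted model*: it simulates datasets from the fit, refits, and
returns the 2.5/97.5 percentiles of the recomputed statistic. The interval
therefore describes the null distribution of the statistic; evidence of
overdispersion is an observed point far above `boot_hi`, not an interval
excluding 1 from above.

## Bayesian fitting

`sample_posterior()` implements the hierarchical Beta-Binomial model with
the population intercepts as explicit latent parameters (one per
population), the JAGS-style formulation, making it algorithmically
independent of the quadrature fits — the two routes cross-validate each
other in the tests. The sampler is adaptive random-walk
Metropolis-within-Gibbs (no closed-form full conditionals exist for this
model): blocks are each fixed effect, each latent intercept, $\sigma_{pop}$
on its natural scale, and $\log \phi$ with the Jacobian correction.
Proposal scales adapt every 50 iterations during burn-in toward a 20–45%
acceptance band and are frozen afterwards, preserving detailed balance for
the retained draws. Default priors: Normal(0, precision 0.001) on the
location parameters, Uniform(0, 10) on $\sigma_{pop}$, Gamma(0.001, 0.001)
on $\phi$; `prior_spec(alt = TRUE)` swaps the latter two for prior
sensitivity checks. The default run is 20,000 iterations, burn-in 2,000,
thinning 20, two overdispersed-start chains — 900 retained draws per chain —
and convergence is assessed with the classic Gelman–Rubin potential scale
reduction factor (`gelman_rubin()`, acceptance bound 1.05).

## Problem sizes and reproducibility

The package's own validation runs at a "desk" scale chosen as its standard
preset: 200 replicates per scenario/model cell for the recovery tables and
100 for the dispersion calibration (the headline study scale in the
literature this mirrors is 1,000 replicates; `default_study_design()`
defaults to that). Every replicated run derives per-replicate seeds
deterministically from one master seed, so serial and parallel executions
agree draw for draw; `scripts/acceptance.R` regenerates the full desk-scale
reproduction from a single `--seed`.

## Known limitations

* Only balanced designs are generated; unbalanced group sizes are out of
  scope.
* No OLRE + Beta-Binomial combined family, random slopes, crossed random
  effects, or non-logit links.
* Standard errors of single fits are not computed (all inference in the
  study design is across replicates); the Hessian is available to add them.
* The Pearson-dispersion calibration of the base model on strongly
  Beta-Binomial-mixed data has analytic expectation
  $1 + (c-1)\phi/(1+\phi)$ ($\approx 3.7$ at $c = 5, \phi = 2$), so the
  statistic is a blunt instrument for distinguishing moderate from strong
  overdispersion there; see the test suite for what is actually asserted.
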