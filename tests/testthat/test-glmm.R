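# Marginal likelihood (quadrature vs brute force) and ML fitting.

test_that("model_spec rejects OLRE with the Beta-Binomial family", {
  expect_error(model_spec("beta_binomial", olre = TRUE), "OLRE")
  expect_error(glmm_control(gh_pop = 4), "orders")
})

test_that("quadrature equals the GLM likelihood at zero variance components", {
  d <- toy_dataset()
  p <- toy_params(sigma_pop = 0)
  eta <- p$mu_pop + p$beta_prey * d$prey + p$beta_bodysize * d$bodysize
  glm_ll <- sum(dbinom(d$hatched, d$clutch, plogis(eta), log = TRUE))
  expect_equal(loglik_marginal(p, d, model_spec("binomial")), glm_ll,
               tolerance = 1e-10)
  expect_equal(loglik_marginal(c(p, sigma_eps = 0), d,
                               model_spec("binomial", olre = TRUE)),
               glm_ll, tolerance = 1e-10)
  expect_equal(loglik_bruteforce(p, d, model_spec("binomial")), glm_ll,
               tolerance = 1e-10)
})

test_that("Beta-Binomial likelihood is continuous at the Binomial limit", {
  d <- toy_dataset()
  p <- toy_params()
  ll_bin <- loglik_marginal(p, d, model_spec("binomial"))
  ll_bb <- loglik_marginal(c(p, phi = 1e-10), d, model_spec("beta_binomial"))
  expect_equal(ll_bb, ll_bin, tolerance = 1e-6)
})

test_that("quadrature matches the brute-force oracle on the toy fixture", {
  d <- toy_dataset()
  p <- toy_params()
  # one latent dimension: order >= 15 already reaches 1e-6
  for (cs in list(list(spec = model_spec("binomial"), params = p),
                  list(spec = model_spec("beta_binomial"),
                       params = c(p, phi = 1)))) {
    oracle <- loglik_bruteforce(cs$params, d, cs$spec)
    for (order in c(15, 20, 30)) {
      ll <- loglik_marginal(cs$params, d, cs$spec,
                            glmm_control(gh_pop = order, gh_olre = order))
      expect_lt(abs(ll - oracle), 1e-6,
                label = sprintf("|quadrature - oracle| %s order=%d",
                                cs$spec$family, order))
    }
  }
  # nested OLRE integral converges more slowly: errors shrink monotonically
  # with the order and reach 1e-6 by order 40
  spec_olre <- model_spec("binomial", olre = TRUE)
  p_olre <- c(p, sigma_eps = 1.5)
  oracle <- loglik_bruteforce(p_olre, d, spec_olre)
  errs <- vapply(c(15, 20, 30, 40), function(order)
    abs(loglik_marginal(p_olre, d, spec_olre,
                        glmm_control(gh_pop = order, gh_olre = order)) -
          oracle), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-6)
})

test_that("the brute-force oracle itself has converged (Cauchy check)", {
  d <- toy_dataset()
  p <- toy_params()
  for (spec in list(model_spec("binomial"), model_spec("beta_binomial"))) {
    pp <- if (spec$family == "beta_binomial") c(p, phi = 1) else p
    a <- loglik_bruteforce(pp, d, spec, grid_n = 1201)
    b <- loglik_bruteforce(pp, d, spec, grid_n = 2401)
    expect_lt(abs(a - b), 1e-8)
  }
  expect_error(loglik_bruteforce(p, simulate_dataset(
    scenario_config("beta_binomial", phi = 1, seed = 1)),
    model_spec("binomial")), "restricted")
})

test_that("ML fit recovers the prey slope on large correctly specified data", {
  cfg <- scenario_config("od_binomial", sigma_eps = 0, n_populations = 20,
                         n_per_population = 100, clutch_size = 10, seed = 31)
  d <- simulate_dataset(cfg)
  f <- fit_ml(d, model_spec("binomial"))
  expect_true(f$converged)
  expect_lt(abs(f$beta_prey - 0.6), 0.05)
  expect_lt(abs(f$mu_pop - (-1)), 0.5)
})

test_that("ML point dominates the generating truth on the fitted family", {
  set.seed(41)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config("beta_binomial", phi = 1, n_populations = 4,
                           n_per_population = 15, clutch_size = 5)
    d <- simulate_dataset(cfg)
    spec <- model_spec("beta_binomial")
    f <- fit_ml(d, spec)
    truth_ll <- loglik_marginal(list(mu_pop = -1, beta_prey = 0.6,
                                     beta_bodysize = -0.01, sigma_pop = 0.5,
                                     phi = 1), d, spec)
    if (f$loglik >= truth_ll - 1e-8) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("the OLRE model never scores below its Binomial submodel", {
  set.seed(42)
  for (r in 1:5) {
    cfg <- scenario_config("od_binomial", sigma_eps = sample(c(0.1, 1.5, 3), 1),
                           n_populations = 5, n_per_population = 10)
    d <- simulate_dataset(cfg)
    base <- fit_ml(d, model_spec("binomial"))
    olre <- fit_ml(d, model_spec("binomial", olre = TRUE))
    expect_gte(olre$loglik, base$loglik - 1e-6)
  }
})

test_that("fits agree with independent implementations (lme4, glmmTMB)", {
  skip_if_not_installed("glmmTMB")
  skip_if_not_installed("lme4")
  cfg <- scenario_config("beta_binomial", phi = 2, n_populations = 10,
                         n_per_population = 40, clutch_size = 5, seed = 77)
  d <- simulate_dataset(cfg)
  f <- fit_ml(d, model_spec("beta_binomial"))
  g <- glmmTMB::glmmTMB(
    cbind(hatched, clutch - hatched) ~ prey + bodysize + (1 | population),
    family = glmmTMB::betabinomial(), data = as.data.frame(d))
  fe <- glmmTMB::fixef(g)$cond
  expect_equal(f$mu_pop, unname(fe[1]), tolerance = 1e-3)
  expect_equal(f$beta_prey, unname(fe[2]), tolerance = 1e-3)
  expect_equal(f$beta_bodysize, unname(fe[3]), tolerance = 1e-3)
  # glmmTMB parameterizes the intra-observation correlation as 1/(1+phi_tmb)
  expect_equal(f$phi, 1 / glmmTMB::sigma(g), tolerance = 0.02)
  expect_equal(f$sigma_pop,
               sqrt(glmmTMB::VarCorr(g)$cond$population[1]), tolerance = 0.02)

  cfg2 <- scenario_config("od_binomial", sigma_eps = 1.5, n_populations = 8,
                          n_per_population = 30, clutch_size = 5, seed = 78)
  d2 <- as.data.frame(simulate_dataset(cfg2))
  f2 <- fit_ml(d2, model_spec("binomial", olre = TRUE))
  d2$obs <- seq_len(nrow(d2))
  m2 <- lme4::glmer(
    cbind(hatched, clutch - hatched) ~ prey + bodysize + (1 | population) +
      (1 | obs), family = binomial(), data = d2)
  fe2 <- lme4::fixef(m2)
  # Laplace vs exact quadrature: loose agreement expected
  expect_equal(f2$beta_prey, unname(fe2[2]), tolerance = 0.05)
  expect_equal(f2$mu_pop, unname(fe2[1]), tolerance = 0.1)
})

test_that("failed fits are reported, not raised, and serialize to JSON", {
  cfg <- scenario_config("beta_binomial", phi = 2, n_populations = 2,
                         n_per_population = 4, clutch_size = 2, seed = 55)
  d <- simulate_dataset(cfg)
  f <- fit_ml(d, model_spec("beta_binomial"))
  expect_s3_class(f, "odb_fit")
  expect_type(f$converged, "logical")
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$family, "beta_binomial")
  expect_equal(js$loglik, f$loglik, tolerance = 1e-12)
})
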