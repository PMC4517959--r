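# Scenario configuration, covariate/data simulation, CSV round trips.

test_that("inverse logit is correct and symmetric", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(-1), 0.26894, tolerance = 1e-5)
  x <- c(-3, -0.7, 0.1, 2.5)
  expect_equal(inv_logit(x) + inv_logit(-x), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diff(inv_logit(seq(-5, 5, 0.5))) > 0))
})

test_that("scenario_config enforces mechanism/parameter pairing", {
  expect_error(scenario_config("beta_binomial"), "phi")
  expect_error(scenario_config("od_binomial"), "sigma_eps")
  expect_error(scenario_config("beta_binomial", phi = 2, sigma_eps = 1),
               "sigma_eps")
  expect_error(scenario_config("beta_binomial", phi = -1), "phi")
  expect_error(scenario_config("od_binomial", sigma_eps = 3,
                               n_populations = 0), "counts")
  cfg <- scenario_config("od_binomial", sigma_eps = 3)
  expect_s3_class(cfg, "scenario_config")
  expect_null(cfg$phi)
})

test_that("covariates are balanced, centered and reproducible", {
  cfg <- scenario_config("beta_binomial", phi = 2, n_populations = 3,
                         n_per_population = 20)
  set.seed(5)
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov), 60)
  expect_equal(as.vector(table(cov$population)), rep(20, 3))
  expect_true(all(abs(cov$bodysize) <= 10))
  set.seed(5)
  expect_identical(cov, simulate_covariates(cfg))
  # the body-size effect spans ~4 percentage points of hatch rate
  expect_lt(abs(inv_logit(-1 + 0.1) - inv_logit(-1 - 0.1) - 0.039), 1e-3)
})

test_that("linear predictor maps covariates and intercepts correctly", {
  cov <- data.frame(population = c(1L, 1L, 2L), prey = c(0, 0, 0),
                    bodysize = c(0, 0, 0))
  tr <- truth_params(mu_pop = -1, sigma_pop = 0)
  expect_equal(linear_predictor(cov, tr, c(-1, -1)), rep(-1, 3))
  cov1 <- data.frame(population = 1L, prey = 1, bodysize = 0)
  expect_equal(linear_predictor(cov1, truth_params(), -1), -0.4)
  # elementwise: permuting rows permutes outputs
  set.seed(8)
  cov <- data.frame(population = sample(1:2, 6, TRUE), prey = rnorm(6),
                    bodysize = runif(6, -10, 10))
  eta <- linear_predictor(cov, truth_params(), c(-1.2, -0.3))
  perm <- sample(6)
  expect_equal(linear_predictor(cov[perm, ], truth_params(), c(-1.2, -0.3)),
               eta[perm])
  expect_error(linear_predictor(data.frame(population = 3L, prey = 0,
                                           bodysize = 0),
                                truth_params(), c(-1, -1)), "intercept")
})

test_that("simulate_dataset honors the design and the mechanisms", {
  cfg <- scenario_config("beta_binomial", phi = 2, n_populations = 10,
                         n_per_population = 20, clutch_size = 5, seed = 3)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d), 200)
  expect_true(all(d$hatched >= 0 & d$hatched <= 5))
  expect_equal(length(attr(d, "pop_intercepts")), 10)
  expect_identical(as.data.frame(simulate_dataset(cfg)), as.data.frame(d))
  expect_error(scenario_config("not_a_mechanism", phi = 1))

  # degenerate truth: mean hatch rate equals inv_logit(-1)
  tr0 <- truth_params(mu_pop = -1, sigma_pop = 0, beta_prey = 0,
                      beta_bodysize = 0)
  cfg0 <- scenario_config("od_binomial", sigma_eps = 0, n_populations = 1,
                          n_per_population = 10000, clutch_size = 5,
                          truth = tr0, seed = 4)
  d0 <- simulate_dataset(cfg0)
  p0 <- plogis(-1)
  se <- sqrt(p0 * (1 - p0) / (5 * 10000))
  expect_lt(abs(mean(d0$hatched / d0$clutch) - p0), 3 * se)

  # both mechanisms degenerate to the same Binomial law at zero dispersion
  cfg_bb0 <- scenario_config("beta_binomial", phi = 0, n_populations = 2,
                             n_per_population = 3000, clutch_size = 5,
                             truth = tr0)
  cfg_od0 <- scenario_config("od_binomial", sigma_eps = 0, n_populations = 2,
                             n_per_population = 3000, clutch_size = 5,
                             truth = tr0)
  set.seed(9); a <- simulate_dataset(cfg_bb0)
  set.seed(9); b <- simulate_dataset(cfg_od0)
  ks <- suppressWarnings(ks.test(a$hatched, b$hatched))
  expect_gt(ks$p.value, 1e-4)
})

test_that("overdispersion grows along the scenario ladders", {
  tr <- truth_params(beta_prey = 0, beta_bodysize = 0, sigma_pop = 0)
  # od mechanism: logit-scale variance of population means grows in sigma_eps
  set.seed(21)
  lvar <- vapply(c(0.1, 1.5, 3), function(s) {
    cfg <- scenario_config("od_binomial", sigma_eps = s, n_populations = 50,
                           n_per_population = 50, clutch_size = 10, truth = tr)
    d <- simulate_dataset(cfg)
    pm <- tapply((d$hatched + 0.5) / (d$clutch + 1), d$population, mean)
    var(qlogis(pm))
  }, numeric(1))
  expect_true(all(diff(lvar) > 0))
  # bb mechanism: per-row variance inflated by 1 + (c-1) phi/(1+phi)
  phi <- 1
  cfg <- scenario_config("beta_binomial", phi = phi, n_populations = 1,
                         n_per_population = 40000, clutch_size = 5,
                         truth = tr, seed = 22)
  d <- simulate_dataset(cfg)
  p <- plogis(-1)
  target <- 5 * p * (1 - p) * (1 + 4 * phi / (1 + phi))
  expect_lt(abs(var(d$hatched) / target - 1), 0.05)
})

test_that("CSV round trip is lossless and parsing is validated", {
  cfg <- scenario_config("beta_binomial", phi = 2, n_populations = 3,
                         n_per_population = 5, seed = 6)
  d <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(as.data.frame(d2), as.data.frame(d)[names(d2)],
               tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("population,prey,bodysize,clutch,hatched",
               "1,0.1,2,5,3", "1,0.2,1,5,6"), bad)
  expect_error(read_dataset(bad), "row 2")
  writeLines("population,prey,bodysize,clutch,hatched", bad)
  expect_error(read_dataset(bad), "no data rows")
  writeLines(c("population,prey", "1,0.1"), bad)
  expect_error(read_dataset(bad), "missing column")
})

test_that("scenario YAML round trip preserves the configuration", {
  cfg <- scenario_config("od_binomial", sigma_eps = 1.5, n_populations = 5,
                         n_per_population = 12, clutch_size = 4,
                         truth = truth_params(mu_pop = -0.5), seed = 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  cfg2 <- read_scenario(path)
  expect_equal(cfg2[c("mechanism", "sigma_eps", "n_populations",
                      "n_per_population", "clutch_size")],
               cfg[c("mechanism", "sigma_eps", "n_populations",
                     "n_per_population", "clutch_size")])
  expect_equal(cfg2$truth$mu_pop, -0.5)
})
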