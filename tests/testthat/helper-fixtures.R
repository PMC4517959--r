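# Shared fixtures for the test suite. The toy dataset is small enough for
# the dense brute-force likelihood oracle (<= 3 populations, <= 10 rows).

toy_dataset <- function() {
  structure(
    data.frame(
      population = c(1L, 1L, 2L),
      prey = c(0.5, -1.0, 0.2),
      bodysize = c(2.0, -4.0, 7.0),
      clutch = c(5L, 5L, 4L),
      hatched = c(3L, 1L, 0L)
    ),
    class = c("odb_dataset", "data.frame")
  )
}

toy_params <- function(sigma_pop = 0.5) {
  list(mu_pop = -1, beta_prey = 0.6, beta_bodysize = -0.01,
       sigma_pop = sigma_pop)
}

# a fit object with known parameters, for exercising the dispersion
# statistic on hand-constructed data
manual_fit <- function(mu_pop = 0, beta_prey = 0, beta_bodysize = 0,
                       sigma_pop = 0, n_obs, n_params = 1L,
                       spec = model_spec("binomial")) {
  structure(list(mu_pop = mu_pop, beta_prey = beta_prey,
                 beta_bodysize = beta_bodysize, sigma_pop = sigma_pop,
                 loglik = 0, converged = TRUE, n_obs = n_obs,
                 n_params = n_params, spec = spec),
            class = "odb_fit")
}

quiet_fit_frame <- function(betas) {
  # minimal list of odb_fit-like objects with given beta_bodysize values
  lapply(betas, function(b)
    structure(list(mu_pop = -1, beta_prey = 0.6, beta_bodysize = b,
                   sigma_pop = 0.5, loglik = 0, converged = TRUE,
                   n_obs = 10L, n_params = 4L,
                   spec = model_spec("binomial")), class = "odb_fit"))
}
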