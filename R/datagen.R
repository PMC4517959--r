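#' True generating parameters for a simulation
#'
#' Fixed-effect and variance-component truth used by the data generator.
#' Defaults are the study conditions used throughout the package: a grand
#' intercept of -1 on the logit scale (baseline hatch rate ~0.27),
#' between-population SD 0.5, a strong positive prey effect (0.6 per SD of
#' prey) and a weak negative body-size effect (-0.01 per unit, ~4 percentage
#' points of hatch rate across the body-size range).
#'
#' @param mu_pop logit-scale grand intercept.
#' @param sigma_pop SD of population intercepts, `>= 0`.
#' @param beta_prey slope per unit of the prey covariate.
#' @param beta_bodysize slope per unit of the body-size covariate.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(mu_pop = -1, sigma_pop = 0.5,
                         beta_prey = 0.6, beta_bodysize = -0.01) {
  if (sigma_pop < 0) stop("'sigma_pop' must be >= 0")
  structure(list(mu_pop = mu_pop, sigma_pop = sigma_pop,
                 beta_prey = beta_prey, beta_bodysize = beta_bodysize),
            class = "truth_params")
}

#' Define one simulation scenario
#'
#' A scenario fixes the overdispersion mechanism and level, the design
#' (number of populations, individuals per population, clutch size) and the
#' generating truth. Mechanism `"beta_binomial"` mixes the Binomial
#' probability through a Beta distribution with dispersion `phi`; mechanism
#' `"od_binomial"` adds Normal(0, `sigma_eps`^2) noise to the logit-scale
#' linear predictor of every observation. Exactly one of `phi` / `sigma_eps`
#' is used, matching the mechanism.
#'
#' @param mechanism `"beta_binomial"` or `"od_binomial"`.
#' @param phi Beta-Binomial dispersion (used when mechanism is
#'   `"beta_binomial"`); `>= 0`, 0 meaning no overdispersion.
#' @param sigma_eps SD of logit-scale observation noise (mechanism
#'   `"od_binomial"`); `>= 0`.
#' @param n_populations number of populations J (`>= 1`).
#' @param n_per_population individuals per population (`>= 1`; balanced
#'   design).
#' @param clutch_size number of Binomial trials per individual (constant).
#' @param truth a [truth_params()] object.
#' @param seed optional integer; when set, [simulate_dataset()] seeds the
#'   RNG with it before drawing.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(mechanism = c("beta_binomial", "od_binomial"),
                            phi = NULL, sigma_eps = NULL,
                            n_populations = 10, n_per_population = 20,
                            clutch_size = 5, truth = truth_params(),
                            seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "beta_binomial") {
    if (is.null(phi)) stop("mechanism 'beta_binomial' requires 'phi'")
    if (!is.null(sigma_eps)) stop("'sigma_eps' is not used by mechanism 'beta_binomial'")
    if (phi < 0) stop("'phi' must be >= 0")
  } else {
    if (is.null(sigma_eps)) stop("mechanism 'od_binomial' requires 'sigma_eps'")
    if (!is.null(phi)) stop("'phi' is not used by mechanism 'od_binomial'")
    if (sigma_eps < 0) stop("'sigma_eps' must be >= 0")
  }
  if (n_populations < 1 || n_per_population < 1 || clutch_size < 1)
    stop("design counts must all be >= 1")
  if (!inherits(truth, "truth_params")) truth <- do.call(truth_params, truth)
  structure(list(mechanism = mechanism, phi = phi, sigma_eps = sigma_eps,
                 n_populations = as.integer(n_populations),
                 n_per_population = as.integer(n_per_population),
                 clutch_size = as.integer(clutch_size),
                 truth = truth, seed = seed),
            class = "scenario_config")
}

#' Inverse logit link
#'
#' Maps a logit-scale linear predictor back to a probability,
#' `1 / (1 + exp(-x))`.
#'
#' @param x numeric vector.
#' @return probabilities strictly inside (0, 1) for finite `x`.
#' @export
inv_logit <- function(x) plogis(x)

#' Draw the covariate columns of a scenario
#'
#' Population labels are assigned in consecutive balanced blocks
#' (`n_per_population` rows per population). Prey is i.i.d. standard normal;
#' body size is i.i.d. uniform on \[-10, 10\], so that the default body-size
#' slope of -0.01 spans about 0.2 logits (~4 percentage points of hatch
#' rate) from the smallest to the largest individual.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `population` (integer), `prey`,
#'   `bodysize`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  J <- config$n_populations
  n <- config$n_per_population
  data.frame(
    population = rep(seq_len(J), each = n),
    prey = rnorm(J * n),
    bodysize = runif(J * n, -10, 10)
  )
}

#' Logit-scale linear predictor
#'
#' `alpha[population] + beta_prey * prey + beta_bodysize * bodysize`, one
#' value per row.
#'
#' @param covariates data.frame with columns `population`, `prey`,
#'   `bodysize`.
#' @param truth a [truth_params()] object (slopes are taken from it).
#' @param pop_intercepts numeric vector of population intercepts, indexed by
#'   the population labels appearing in `covariates`.
#' @return numeric vector of logits.
#' @export
linear_predictor <- function(covariates, truth, pop_intercepts) {
  j <- as.integer(covariates$population)
  if (any(j < 1L) || any(j > length(pop_intercepts)))
    stop("population label without a matching intercept")
  pop_intercepts[j] + truth$beta_prey * covariates$prey +
    truth$beta_bodysize * covariates$bodysize
}

#' Simulate one dataset under a scenario
#'
#' Draws population intercepts `alpha_j ~ Normal(mu_pop, sigma_pop^2)`,
#' builds the linear predictor, and draws hatched counts either from the
#' Beta-Binomial compound distribution (`mechanism = "beta_binomial"`) or
#' from a Binomial whose logit has had Normal(0, `sigma_eps`^2) noise added
#' per observation (`mechanism = "od_binomial"`). The latent population
#' intercepts are retained as an attribute for testing.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer overriding `config$seed`; when neither is
#'   given the current RNG stream is used.
#' @return a data.frame of class `odb_dataset` with columns `population`,
#'   `prey`, `bodysize`, `clutch`, `hatched`; attributes `config` and
#'   `pop_intercepts`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  truth <- config$truth
  J <- config$n_populations
  alpha <- rnorm(J, truth$mu_pop, truth$sigma_pop)
  cov <- simulate_covariates(config)
  eta <- linear_predictor(cov, truth, alpha)
  cl <- rep.int(config$clutch_size, nrow(cov))
  if (config$mechanism == "od_binomial") {
    eps <- if (config$sigma_eps > 0) rnorm(nrow(cov), 0, config$sigma_eps) else 0
    hatched <- rbinom(nrow(cov), cl, plogis(eta + eps))
  } else {
    hatched <- betabinom_sample(cl, plogis(eta), config$phi)
  }
  out <- cbind(cov, clutch = cl, hatched = hatched)
  structure(out, config = config, pop_intercepts = alpha,
            class = c("odb_dataset", "data.frame"))
}

dataset_columns <- c("population", "prey", "bodysize", "clutch", "hatched")

validate_dataset <- function(df, where = "dataset") {
  missing_cols <- setdiff(dataset_columns, names(df))
  if (length(missing_cols))
    stop(where, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop(where, ": no data rows")
  bad <- which(!is.finite(df$clutch) | !is.finite(df$hatched) |
                 df$hatched < 0 | df$hatched > df$clutch)
  if (length(bad))
    stop(where, ": invalid hatched/clutch at row ", bad[1L],
         " (hatched must lie in [0, clutch])")
  df
}

#' Write / read a dataset as CSV
#'
#' The on-disk format is a plain comma-separated file with header
#' `population,prey,bodysize,clutch,hatched`. Reading validates every row
#' (`0 <= hatched <= clutch`) and reports the first offending row.
#'
#' @param dataset an `odb_dataset` or compatible data.frame.
#' @param path file path.
#' @return `read_dataset` returns an `odb_dataset`; `write_dataset` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(as.data.frame(dataset))
  write.csv(as.data.frame(dataset)[dataset_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop("could not parse '", path, "': ", conditionMessage(e)))
  df <- validate_dataset(df, where = path)
  df$population <- as.integer(factor(df$population))
  structure(df[dataset_columns], class = c("odb_dataset", "data.frame"))
}

#' Read / write a scenario configuration as YAML
#'
#' Field names mirror [scenario_config()].
#'
#' @param path YAML file path.
#' @param config a [scenario_config()].
#' @return `read_scenario` returns a `scenario_config`.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  truth <- if (!is.null(x$truth)) do.call(truth_params, x$truth) else truth_params()
  scenario_config(mechanism = x$mechanism, phi = x$phi,
                  sigma_eps = x$sigma_eps,
                  n_populations = x$n_populations %||% 10,
                  n_per_population = x$n_per_population %||% 20,
                  clutch_size = x$clutch_size %||% 5,
                  truth = truth, seed = x$seed)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$truth <- unclass(x$truth)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
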