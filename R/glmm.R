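#' Specify a mixed-model family
#'
#' Three model families are supported, all with a population random
#' intercept: plain Binomial, Binomial with an observation-level random
#' effect (OLRE; a Normal logit-scale intercept unique to each row), and
#' Beta-Binomial. OLRE is only combined with the Binomial family.
#'
#' @param family `"binomial"` or `"beta_binomial"`.
#' @param olre logical; add an observation-level random effect
#'   (Binomial family only).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("binomial", "beta_binomial"), olre = FALSE) {
  family <- match.arg(family)
  if (olre && family != "binomial")
    stop("an OLRE is only supported with family = 'binomial'")
  structure(list(family = family, olre = olre), class = "model_spec")
}

#' Quadrature and optimizer settings for [fit_ml()]
#'
#' @param gh_pop Gauss-Hermite order for the population-intercept integral
#'   (`>= 5`).
#' @param gh_olre Gauss-Hermite order for the inner observation-level
#'   integral (`>= 5`).
#' @param restarts maximum number of jittered optimizer restarts after a
#'   failed fit.
#' @return list of settings.
#' @export
glmm_control <- function(gh_pop = 20, gh_olre = 15, restarts = 3) {
  if (gh_pop < 5 || gh_olre < 5)
    stop("quadrature orders below 5 are not allowed")
  list(gh_pop = as.integer(gh_pop), gh_olre = as.integer(gh_olre),
       restarts = as.integer(restarts))
}

.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(order)
  .gh_cache[[key]]
}

# spec: family / olre; params: list or named vector with mu_pop, beta_prey,
# beta_bodysize, sigma_pop and (sigma_eps | phi) as applicable
family_code <- function(spec) {
  if (spec$family == "beta_binomial") 2L else if (spec$olre) 1L else 0L
}

dispersion_of <- function(params, spec) {
  if (spec$family == "beta_binomial") params[["phi"]]
  else if (spec$olre) params[["sigma_eps"]]
  else 0
}

#' Marginal log-likelihood via Gauss-Hermite quadrature
#'
#' Integrates the population random intercept out of the likelihood with
#' non-adaptive Gauss-Hermite quadrature; for the OLRE model each row's
#' observation-level effect is integrated by a nested inner quadrature
#' (valid because, given the population intercept, the row effects are
#' independent and the integrand factors over rows). For the Beta-Binomial
#' family the per-row term is the Beta-Binomial pmf at `p = inv_logit(eta)`
#' with shapes `p/phi`, `(1-p)/phi`.
#'
#' @param params named list/vector with `mu_pop`, `beta_prey`,
#'   `beta_bodysize`, `sigma_pop`, plus `sigma_eps` (OLRE) or `phi`
#'   (Beta-Binomial).
#' @param dataset an `odb_dataset`.
#' @param spec a [model_spec()].
#' @param control a [glmm_control()].
#' @return the marginal log-likelihood (scalar).
#' @export
loglik_marginal <- function(params, dataset, spec, control = glmm_control()) {
  params <- as.list(params)
  dataset <- validate_dataset(as.data.frame(dataset))
  eta0 <- params$mu_pop + params$beta_prey * dataset$prey +
    params$beta_bodysize * dataset$bodysize
  if (any(!is.finite(eta0))) stop("non-finite linear predictor")
  if (params$sigma_pop < 0) stop("'sigma_pop' must be >= 0")
  disp <- dispersion_of(params, spec)
  if (!is.null(disp) && disp < 0) stop("dispersion parameter must be >= 0")
  pop <- as.integer(factor(dataset$population))
  g1 <- gh_rule(control$gh_pop)
  g2 <- gh_rule(control$gh_olre)
  marginal_loglik_cpp(as.numeric(dataset$hatched), as.numeric(dataset$clutch),
                      eta0, pop - 1L, max(pop),
                      params$sigma_pop, family_code(spec),
                      if (is.null(disp)) 0 else disp,
                      g1$x, g1$w, g2$x, g2$w)
}

#' Brute-force marginal log-likelihood (test oracle)
#'
#' Computes the same quantity as [loglik_marginal()] by dense deterministic
#' trapezoid integration over the latent effects on a +/- 8 SD grid. Cost
#' grows with `grid_n^2` per row for the OLRE model, so the dataset is
#' restricted to at most 3 populations and 10 rows.
#'
#' @inheritParams loglik_marginal
#' @param grid_n number of grid points per latent dimension (>= 51).
#' @return the marginal log-likelihood (scalar).
#' @export
loglik_bruteforce <- function(params, dataset, spec, grid_n = 2001) {
  params <- as.list(params)
  dataset <- validate_dataset(as.data.frame(dataset))
  pop <- as.integer(factor(dataset$population))
  if (max(pop) > 3L || nrow(dataset) > 10L)
    stop("brute-force oracle is restricted to <= 3 populations and <= 10 rows")
  if (grid_n < 51) stop("'grid_n' too small for a dense grid")
  eta0 <- params$mu_pop + params$beta_prey * dataset$prey +
    params$beta_bodysize * dataset$bodysize
  h <- dataset$hatched; cl <- dataset$clutch
  sp <- params$sigma_pop
  disp <- dispersion_of(params, spec)

  # log of trapezoid integral of exp(lf) weighted by Normal(0, s) density
  log_trapz_norm <- function(lf, grid, s) {
    lw <- dnorm(grid, 0, s, log = TRUE)
    v <- lf + lw
    m <- max(v)
    dx <- grid[2L] - grid[1L]
    w <- rep(1, length(grid)); w[c(1L, length(grid))] <- 0.5
    m + log(sum(w * exp(v - m)) * dx)
  }

  row_loglik <- function(eta_i, h_i, c_i) {
    # log f(h_i | alpha-offset already inside eta_i), integrating any
    # observation-level effect
    if (spec$family == "beta_binomial" && disp > 0) {
      p <- pmin(pmax(plogis(eta_i), 1e-12), 1 - 1e-12)
      lchoose(c_i, h_i) + lbeta(h_i + p / disp, c_i - h_i + (1 - p) / disp) -
        lbeta(p / disp, (1 - p) / disp)
    } else if (spec$family == "binomial" && spec$olre && disp > 0) {
      eg <- seq(-8 * disp, 8 * disp, length.out = grid_n)
      vapply(seq_along(eta_i), function(i) {
        lf <- dbinom(h_i[i], c_i[i], plogis(eta_i[i] + eg), log = TRUE)
        log_trapz_norm(lf, eg, disp)
      }, numeric(1))
    } else {
      dbinom(h_i, c_i, plogis(eta_i), log = TRUE)
    }
  }

  per_pop <- function(j) {
    idx <- which(pop == j)
    if (sp <= 0)
      return(sum(row_loglik(eta0[idx], h[idx], cl[idx])))
    ag <- seq(-8 * sp, 8 * sp, length.out = grid_n)
    lf <- rowSums(vapply(idx, function(i)
      row_loglik(eta0[i] + ag, rep(h[i], grid_n), rep(cl[i], grid_n)),
      numeric(grid_n)))
    log_trapz_norm(lf, ag, sp)
  }
  sum(vapply(seq_len(max(pop)), per_pop, numeric(1)))
}

pack_start <- function(dataset, spec) {
  g <- glm(cbind(hatched, clutch - hatched) ~ prey + bodysize,
           family = binomial(), data = dataset)
  th <- c(coef(g), log(0.5))
  if (spec$olre || spec$family == "beta_binomial") th <- c(th, log(0.5))
  unname(th)
}

unpack_params <- function(theta, spec) {
  p <- list(mu_pop = theta[1L], beta_prey = theta[2L],
            beta_bodysize = theta[3L], sigma_pop = exp(theta[4L]))
  if (spec$family == "beta_binomial") p$phi <- exp(theta[5L])
  else if (spec$olre) p$sigma_eps <- exp(theta[5L])
  p
}

#' Fit a Binomial-type mixed model by marginal maximum likelihood
#'
#' Maximizes [loglik_marginal()] over the fixed effects and the
#' log-transformed variance/dispersion parameters with `nlminb`, starting
#' from a plain-GLM fit for the fixed effects and 0.5 for SDs/dispersion.
#' For models with a dispersion component the plain Binomial fit is also
#' used as a fallback start, which guarantees the fitted OLRE model never
#' scores below its Binomial submodel. On optimizer failure up to
#' `control$restarts` jittered restarts are attempted; if all fail the best
#' point found is returned with `converged = FALSE` (no error), so
#' replicated studies can record failure rates. SD estimates below 1e-4 are
#' reported as exactly 0 (a boundary fit).
#'
#' @param dataset an `odb_dataset` (or data.frame with the dataset columns).
#' @param spec a [model_spec()].
#' @param control a [glmm_control()].
#' @return object of class `odb_fit`: list with elements `mu_pop`,
#'   `beta_prey`, `beta_bodysize`, `sigma_pop`, `sigma_eps` or `phi` (as
#'   applicable), `loglik`, `converged`, `n_obs`, `n_params`, `spec`.
#' @examples
#' cfg <- scenario_config("beta_binomial", phi = 2, seed = 1)
#' d <- simulate_dataset(cfg)
#' fit_ml(d, model_spec("beta_binomial"))
#' @export
fit_ml <- function(dataset, spec, control = glmm_control()) {
  dataset <- validate_dataset(as.data.frame(dataset))
  dataset$population <- as.integer(factor(dataset$population))
  has_disp <- spec$olre || spec$family == "beta_binomial"
  nll <- function(theta) {
    p <- unpack_params(theta, spec)
    ll <- loglik_marginal(p, dataset, spec, control)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- c(-Inf, -Inf, -Inf, log(1e-6))
  upper <- c(Inf, Inf, Inf, log(30))
  if (has_disp) { lower <- c(lower, log(1e-6)); upper <- c(upper, log(30)) }

  run_opt <- function(start) {
    res <- tryCatch(nlminb(start, nll, lower = lower, upper = upper,
                           control = list(iter.max = 500, eval.max = 1000)),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) return(NULL)
    res
  }

  start <- pack_start(dataset, spec)
  best <- run_opt(start)
  ok <- !is.null(best) && best$convergence == 0
  tries <- 0L
  while (!ok && tries < control$restarts) {
    tries <- tries + 1L
    cand <- run_opt(start + rnorm(length(start), 0, 0.5))
    if (!is.null(cand) && (is.null(best) || cand$objective < best$objective)) {
      best <- cand
      ok <- best$convergence == 0
    }
  }

  # nesting fallback: a dispersion model must do at least as well as the
  # plain Binomial submodel it contains at the zero-dispersion boundary
  if (has_disp) {
    base <- fit_ml(dataset, model_spec("binomial"), control)
    if (base$converged &&
        (is.null(best) || -best$objective < base$loglik - 1e-8)) {
      alt <- run_opt(c(base$mu_pop, base$beta_prey, base$beta_bodysize,
                       log(max(base$sigma_pop, 1e-6)), log(1e-6)))
      if (!is.null(alt) && (is.null(best) || alt$objective < best$objective)) {
        best <- alt
        ok <- best$convergence == 0
      }
    }
  }

  if (is.null(best)) {
    p <- unpack_params(start, spec)
    ll <- -nll(start)
    ok <- FALSE
  } else {
    p <- unpack_params(best$par, spec)
    ll <- -best$objective
  }
  p$sigma_pop <- if (p$sigma_pop < 1e-4) 0 else p$sigma_pop
  if (!is.null(p$sigma_eps) && p$sigma_eps < 1e-4) p$sigma_eps <- 0
  structure(c(p, list(loglik = ll, converged = ok,
                      n_obs = nrow(dataset),
                      n_params = 4L + as.integer(has_disp),
                      spec = spec)),
            class = "odb_fit")
}

#' @export
print.odb_fit <- function(x, ...) {
  fam <- if (x$spec$family == "beta_binomial") "Beta-Binomial"
         else if (x$spec$olre) "Binomial + OLRE" else "Binomial"
  cat(sprintf("%s mixed model fit by marginal ML (%d obs)\n", fam, x$n_obs))
  cat(sprintf("  mu_pop = %.4f  beta_prey = %.4f  beta_bodysize = %.4f\n",
              x$mu_pop, x$beta_prey, x$beta_bodysize))
  cat(sprintf("  sigma_pop = %.4f", x$sigma_pop))
  if (!is.null(x$sigma_eps)) cat(sprintf("  sigma_eps = %.4f", x$sigma_eps))
  if (!is.null(x$phi)) cat(sprintf("  phi = %.4f", x$phi))
  cat(sprintf("\n  logLik = %.4f  converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

fit_params <- function(fit) {
  p <- list(mu_pop = fit$mu_pop, beta_prey = fit$beta_prey,
            beta_bodysize = fit$beta_bodysize, sigma_pop = fit$sigma_pop)
  if (!is.null(fit$sigma_eps)) p$sigma_eps <- fit$sigma_eps
  if (!is.null(fit$phi)) p$phi <- fit$phi
  p
}

#' Serialize a fit to JSON
#'
#' @param fit an `odb_fit`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  x <- fit[setdiff(names(fit), "spec")]
  x$family <- fit$spec$family
  x$olre <- fit$spec$olre
  if (is.null(path))
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
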