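# Bayesian Beta-Binomial hierarchical model: adaptive random-walk
# Metropolis-within-Gibbs with the population intercepts sampled explicitly
# as latent parameters (one per population), mirroring the JAGS-style
# formulation and providing an algorithmically independent cross-check of
# the quadrature ML fits.

#' Prior specification for the Bayesian Beta-Binomial model
#'
#' Location parameters (`mu_pop`, `beta_prey`, `beta_bodysize`) get
#' uninformative Normal priors with mean 0 and precision 0.001. By default
#' `sigma_pop` is Uniform(0, 10) and `phi` is Gamma(0.001, 0.001); the
#' `alt` flag swaps the two (Uniform on `phi`, Gamma on `sigma_pop`), the
#' standard prior-sensitivity variant.
#'
#' @param alt logical; use the swapped variance-parameter priors.
#' @param location_precision precision of the Normal location priors.
#' @param uniform_upper upper bound of the Uniform prior.
#' @param gamma_shape,gamma_rate Gamma prior parameters.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(alt = FALSE, location_precision = 0.001,
                       uniform_upper = 10, gamma_shape = 0.001,
                       gamma_rate = 0.001) {
  if (location_precision <= 0 || uniform_upper <= 0)
    stop("precision and uniform upper bound must be positive")
  structure(list(alt = alt, location_precision = location_precision,
                 uniform_upper = uniform_upper, gamma_shape = gamma_shape,
                 gamma_rate = gamma_rate), class = "prior_spec")
}

bb_row_loglik <- function(eta, h, cl, phi) {
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  bb_logpmf_cpp(h, cl, p / phi, (1 - p) / phi)
}

log_prior_terms <- function(params, priors) {
  sdl <- 1 / sqrt(priors$location_precision)
  lp <- dnorm(params$mu_pop, 0, sdl, log = TRUE) +
    dnorm(params$beta_prey, 0, sdl, log = TRUE) +
    dnorm(params$beta_bodysize, 0, sdl, log = TRUE)
  unif_lp <- function(x) {
    if (x < 0 || x > priors$uniform_upper) -Inf else -log(priors$uniform_upper)
  }
  gamma_lp <- function(x) {
    if (x <= 0) -Inf
    else dgamma(x, shape = priors$gamma_shape, rate = priors$gamma_rate,
                log = TRUE)
  }
  if (priors$alt) lp + gamma_lp(params$sigma_pop) + unif_lp(params$phi)
  else lp + unif_lp(params$sigma_pop) + gamma_lp(params$phi)
}

#' Log posterior of the Bayesian Beta-Binomial hierarchical model
#'
#' Likelihood with the population intercepts as explicit latent parameters
#' (`alpha_j`, prior `Normal(mu_pop, sigma_pop^2)`) plus the log priors of
#' [prior_spec()]. Returns `-Inf` outside the prior support.
#'
#' @param params named list: `mu_pop`, `beta_prey`, `beta_bodysize`,
#'   `sigma_pop`, `phi`, and `alpha` (vector, one intercept per population).
#' @param dataset an `odb_dataset`.
#' @param priors a [prior_spec()].
#' @return scalar log posterior density (unnormalized).
#' @importFrom stats dgamma
#' @export
log_posterior <- function(params, dataset, priors = prior_spec()) {
  dataset <- validate_dataset(as.data.frame(dataset))
  pop <- as.integer(factor(dataset$population))
  if (length(params$alpha) != max(pop))
    stop("'alpha' must have one element per population")
  lp <- log_prior_terms(params, priors)
  if (!is.finite(lp)) return(-Inf)
  if (params$sigma_pop <= 0) return(-Inf)
  eta <- params$alpha[pop] + params$beta_prey * dataset$prey +
    params$beta_bodysize * dataset$bodysize
  lp + sum(bb_row_loglik(eta, dataset$hatched, dataset$clutch, params$phi)) +
    sum(dnorm(params$alpha, params$mu_pop, params$sigma_pop, log = TRUE))
}

#' Sample the Beta-Binomial hierarchical posterior by adaptive MCMC
#'
#' Random-walk Metropolis-within-Gibbs over blocks (each fixed effect, each
#' latent population intercept, `sigma_pop`, and `log phi`). Proposal scales
#' are tuned during burn-in toward 20-45% acceptance and frozen afterwards
#' (preserving detailed balance for the retained draws). Defaults match a
#' conventional JAGS-style run: 20,000 iterations, burn-in 2,000, thinning
#' 20, two chains, giving 900 retained draws per chain.
#'
#' @param dataset an `odb_dataset`.
#' @param priors a [prior_spec()].
#' @param n_iter total iterations per chain.
#' @param burnin iterations discarded (and used for adaptation).
#' @param thin thinning interval applied after burn-in.
#' @param n_chains number of chains (`>= 2`).
#' @param seed optional integer; chain `k` is seeded with `seed + k`.
#' @return object of class `odb_chains`: list with `draws` (one matrix per
#'   chain, columns `mu_pop`, `beta_prey`, `beta_bodysize`, `sigma_pop`,
#'   `phi`, `alpha_1..J`), `burnin`, `thin`, `n_iter`, `acceptance`.
#' @export
sample_posterior <- function(dataset, priors = prior_spec(),
                             n_iter = 20000, burnin = 2000, thin = 20,
                             n_chains = 2, seed = NULL) {
  dataset <- validate_dataset(as.data.frame(dataset))
  if (n_iter <= burnin) stop("'n_iter' must exceed 'burnin'")
  if (thin < 1) stop("'thin' must be >= 1")
  if (n_chains < 2) stop("at least 2 chains are required")
  n_keep <- (n_iter - burnin) %/% thin
  if (n_keep < 1) stop("no post-thinning draws: increase n_iter or lower thin")
  pop <- as.integer(factor(dataset$population))
  J <- max(pop)
  h <- dataset$hatched; cl <- dataset$clutch
  eta_x <- function(bp, bb) bp * dataset$prey + bb * dataset$bodysize
  pop_idx <- split(seq_along(pop), pop)

  # starting point: plain GLM for the fixed effects
  g <- glm(cbind(hatched, clutch - hatched) ~ prey + bodysize,
           family = binomial(), data = dataset)
  init0 <- c(coef(g)[[1L]], coef(g)[[2L]], coef(g)[[3L]], 0.5, 0.5,
             rep(coef(g)[[1L]], J))
  par_names <- c("mu_pop", "beta_prey", "beta_bodysize", "sigma_pop", "phi",
                 paste0("alpha_", seq_len(J)))
  P <- length(init0)

  run_chain <- function(chain_id) {
    if (!is.null(seed)) set.seed(seed + chain_id)
    # overdispersed starts so the diagnostic is honest
    th <- init0 + c(rnorm(3, 0, 1), abs(rnorm(1, 0, 0.5)), 0, rnorm(J, 0, 1))
    th[4L] <- min(max(th[4L] + 0.1, 0.05), priors$uniform_upper - 0.1)
    th[5L] <- exp(rnorm(1, log(init0[5L]), 0.5))
    names(th) <- par_names
    alpha <- th[6L:(5L + J)]
    ll_rows <- bb_row_loglik(alpha[pop] + eta_x(th[2L], th[3L]), h, cl, th[5L])
    scales <- rep(0.3, P)
    acc <- rep(0L, P); prop <- rep(0L, P)
    win_acc <- rep(0L, P); win_prop <- rep(0L, P)
    draws <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, par_names))
    kept <- 0L

    sd_loc <- 1 / sqrt(priors$location_precision)
    lp_sigma <- function(s) {
      if (priors$alt) {
        if (s <= 0) -Inf else dgamma(s, priors$gamma_shape,
                                     rate = priors$gamma_rate, log = TRUE)
      } else if (s <= 0 || s > priors$uniform_upper) -Inf else 0
    }
    lp_phi <- function(f) {
      if (priors$alt) {
        if (f <= 0 || f > priors$uniform_upper) -Inf else 0
      } else if (f <= 0) -Inf
      else dgamma(f, priors$gamma_shape, rate = priors$gamma_rate, log = TRUE)
    }

    for (it in seq_len(n_iter)) {
      # fixed effects: mu_pop enters only the alpha prior; betas the data
      for (b in 1L:3L) {
        cand <- th[b] + rnorm(1, 0, scales[b])
        if (b == 1L) {
          d <- sum(dnorm(alpha, cand, th[4L], log = TRUE)) -
            sum(dnorm(alpha, th[b], th[4L], log = TRUE)) +
            dnorm(cand, 0, sd_loc, log = TRUE) -
            dnorm(th[b], 0, sd_loc, log = TRUE)
          new_rows <- NULL
        } else {
          bp <- if (b == 2L) cand else th[2L]
          bb <- if (b == 3L) cand else th[3L]
          new_rows <- bb_row_loglik(alpha[pop] + eta_x(bp, bb), h, cl, th[5L])
          d <- sum(new_rows) - sum(ll_rows) +
            dnorm(cand, 0, sd_loc, log = TRUE) -
            dnorm(th[b], 0, sd_loc, log = TRUE)
        }
        prop[b] <- prop[b] + 1L; win_prop[b] <- win_prop[b] + 1L
        if (is.finite(d) && log(runif(1)) < d) {
          th[b] <- cand
          if (!is.null(new_rows)) ll_rows <- new_rows
          acc[b] <- acc[b] + 1L; win_acc[b] <- win_acc[b] + 1L
        }
      }
      # sigma_pop (natural scale)
      cand <- th[4L] + rnorm(1, 0, scales[4L])
      d <- lp_sigma(cand) - lp_sigma(th[4L])
      if (is.finite(d))
        d <- d + sum(dnorm(alpha, th[1L], cand, log = TRUE)) -
          sum(dnorm(alpha, th[1L], th[4L], log = TRUE))
      prop[4L] <- prop[4L] + 1L; win_prop[4L] <- win_prop[4L] + 1L
      if (is.finite(d) && log(runif(1)) < d) {
        th[4L] <- cand; acc[4L] <- acc[4L] + 1L; win_acc[4L] <- win_acc[4L] + 1L
      }
      # phi (log-scale random walk with Jacobian)
      cand <- th[5L] * exp(rnorm(1, 0, scales[5L]))
      d <- lp_phi(cand) - lp_phi(th[5L]) + log(cand) - log(th[5L])
      if (is.finite(d)) {
        new_rows <- bb_row_loglik(alpha[pop] + eta_x(th[2L], th[3L]), h, cl, cand)
        d <- d + sum(new_rows) - sum(ll_rows)
      }
      prop[5L] <- prop[5L] + 1L; win_prop[5L] <- win_prop[5L] + 1L
      if (is.finite(d) && log(runif(1)) < d) {
        th[5L] <- cand; ll_rows <- new_rows
        acc[5L] <- acc[5L] + 1L; win_acc[5L] <- win_acc[5L] + 1L
      }
      # latent intercepts, one at a time (only their rows change)
      eta_fix <- eta_x(th[2L], th[3L])
      for (j in seq_len(J)) {
        b <- 5L + j
        idx <- pop_idx[[j]]
        cand <- alpha[j] + rnorm(1, 0, scales[b])
        new_rows <- bb_row_loglik(cand + eta_fix[idx], h[idx], cl[idx], th[5L])
        d <- sum(new_rows) - sum(ll_rows[idx]) +
          dnorm(cand, th[1L], th[4L], log = TRUE) -
          dnorm(alpha[j], th[1L], th[4L], log = TRUE)
        prop[b] <- prop[b] + 1L; win_prop[b] <- win_prop[b] + 1L
        if (is.finite(d) && log(runif(1)) < d) {
          alpha[j] <- cand; ll_rows[idx] <- new_rows
          acc[b] <- acc[b] + 1L; win_acc[b] <- win_acc[b] + 1L
        }
      }
      th[6L:(5L + J)] <- alpha
      # adapt proposal scales during burn-in only
      if (it <= burnin && it %% 50L == 0L) {
        rate <- ifelse(win_prop > 0, win_acc / win_prop, 0.3)
        scales <- scales * ifelse(rate > 0.45, 1.3,
                                  ifelse(rate < 0.20, 1 / 1.3, 1))
        win_acc[] <- 0L; win_prop[] <- 0L
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- th
      }
    }
    list(draws = draws[seq_len(kept), , drop = FALSE], acceptance = acc / prop)
  }

  chains <- lapply(seq_len(n_chains), run_chain)
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 acceptance = do.call(rbind, lapply(chains, `[[`, "acceptance")),
                 burnin = burnin, thin = thin, n_iter = n_iter),
            class = "odb_chains")
}

#' @export
print.odb_chains <- function(x, ...) {
  cat(sprintf("MCMC chain set: %d chains x %d retained draws (%d params)\n",
              length(x$draws), nrow(x$draws[[1L]]), ncol(x$draws[[1L]])))
  cat("max Gelman-Rubin:", sprintf("%.4f", max(gelman_rubin(x))), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic: with `m` chains of `n`
#' draws, `W` the mean within-chain variance and `B/n` the variance of the
#' chain means, the statistic is `sqrt((((n-1)/n) W + (1 + 1/m) B/n) / W)`.
#' Values near 1 indicate convergence; a common acceptance bound is 1.05.
#'
#' @param chains an `odb_chains` object from [sample_posterior()].
#' @param parameter parameter name; when `NULL` all parameters are returned
#'   as a named vector.
#' @return numeric PSRF value(s).
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  stopifnot(inherits(chains, "odb_chains"))
  if (length(chains$draws) < 2L) stop("at least 2 chains are required")
  pars <- colnames(chains$draws[[1L]])
  if (is.null(parameter)) {
    return(setNames(vapply(pars, function(p) gelman_rubin(chains, p),
                           numeric(1)), pars))
  }
  if (!parameter %in% pars) stop("unknown parameter '", parameter, "'")
  x <- vapply(chains$draws, function(d) d[, parameter],
              numeric(nrow(chains$draws[[1L]])))
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2L, var))
  if (W == 0) stop("zero within-chain variance for '", parameter, "'")
  B_over_n <- var(colMeans(x))
  sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
}

#' Export retained draws as a plain CSV
#'
#' One row per retained draw, one column per parameter, plus a leading
#' `chain` column, for use with external diagnostics.
#'
#' @param chains an `odb_chains` object.
#' @param path file path.
#' @export
write_chains <- function(chains, path) {
  stopifnot(inherits(chains, "odb_chains"))
  tab <- do.call(rbind, lapply(seq_along(chains$draws), function(k)
    cbind(chain = k, as.data.frame(chains$draws[[k]]))))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
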