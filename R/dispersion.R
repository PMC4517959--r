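# Pearson-residual dispersion diagnostics for the mixed-model fits.
# Fitted probabilities are conditional: fixed effects plus the predicted
# population intercept (posterior mode of alpha_j at the ML parameters).

# posterior mode of each population intercept given a fit
predict_intercepts <- function(dataset, fit, control = glmm_control()) {
  spec <- fit$spec
  pop <- as.integer(factor(dataset$population))
  J <- max(pop)
  eta_fix <- fit$beta_prey * dataset$prey + fit$beta_bodysize * dataset$bodysize
  disp <- dispersion_of(fit, spec)
  g2 <- gh_rule(control$gh_olre)

  row_ll <- function(eta, h, cl) {
    if (spec$family == "beta_binomial" && !is.null(disp) && disp > 0) {
      p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
      sum(bb_logpmf_cpp(h, cl, p / disp, (1 - p) / disp))
    } else if (spec$olre && !is.null(disp) && disp > 0) {
      # integrate the row effect by quadrature inside the mode search
      lw <- log(g2$w) - 0.5 * log(pi)
      sum(vapply(seq_along(eta), function(i) {
        v <- lw + dbinom(h[i], cl[i], plogis(eta[i] + sqrt(2) * disp * g2$x),
                         log = TRUE)
        m <- max(v); m + log(sum(exp(v - m)))
      }, numeric(1)))
    } else {
      sum(dbinom(h, cl, pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12), log = TRUE))
    }
  }

  vapply(seq_len(J), function(j) {
    idx <- which(pop == j)
    if (fit$sigma_pop <= 0) return(fit$mu_pop)
    obj <- function(a)
      -(dnorm(a, fit$mu_pop, fit$sigma_pop, log = TRUE) +
          row_ll(a + eta_fix[idx], dataset$hatched[idx], dataset$clutch[idx]))
    optimize(obj, c(fit$mu_pop - 8 * fit$sigma_pop - 5,
                    fit$mu_pop + 8 * fit$sigma_pop + 5))$minimum
  }, numeric(1))
}

#' Pearson-residual dispersion statistic
#'
#' Ratio of the sum of squared Pearson residuals to the residual degrees of
#' freedom: `sum((h - c p)^2 / (c p (1 - p))) / (n_obs - n_params)`, where
#' `p` is the conditional fitted probability (fixed effects plus the
#' predicted population intercept, and, for OLRE fits, the predicted
#' observation-level effect -- the convention of the standard GLMM
#' dispersion checks, under which the OLRE absorbs extra-Binomial
#' variation) and the parameter count includes the variance/dispersion
#' components. Values above 1 indicate overdispersion.
#'
#' @param dataset the data the model was fitted to.
#' @param fit a converged [fit_ml()] result.
#' @param control a [glmm_control()] (used for the OLRE integral inside the
#'   intercept prediction).
#' @return list with `point` (the dispersion ratio) and `residual_df`.
#' @export
pearson_dispersion <- function(dataset, fit, control = glmm_control()) {
  dataset <- validate_dataset(as.data.frame(dataset))
  if (!isTRUE(fit$converged)) stop("dispersion requires a converged fit")
  alpha <- predict_intercepts(dataset, fit, control)
  pop <- as.integer(factor(dataset$population))
  eta <- alpha[pop] + fit$beta_prey * dataset$prey +
    fit$beta_bodysize * dataset$bodysize
  if (fit$spec$olre && !is.null(fit$sigma_eps) && fit$sigma_eps > 0) {
    se <- fit$sigma_eps
    eta <- eta + vapply(seq_along(eta), function(i) {
      optimize(function(e)
        -(dnorm(e, 0, se, log = TRUE) +
            dbinom(dataset$hatched[i], dataset$clutch[i],
                   pmin(pmax(plogis(eta[i] + e), 1e-12), 1 - 1e-12),
                   log = TRUE)),
        c(-8 * se, 8 * se))$minimum
    }, numeric(1))
  }
  p <- plogis(eta)
  if (any(p <= 0) || any(p >= 1))
    stop("degenerate fit: fitted probability of exactly 0 or 1")
  rdf <- fit$n_obs - fit$n_params
  if (rdf < 1) stop("no residual degrees of freedom")
  chisq <- sum((dataset$hatched - dataset$clutch * p)^2 /
                 (dataset$clutch * p * (1 - p)))
  list(point = chisq / rdf, residual_df = rdf)
}

# simulate a response vector from a fitted model on the same covariates
simulate_from_fit <- function(dataset, fit) {
  spec <- fit$spec
  pop <- as.integer(factor(dataset$population))
  alpha <- rnorm(max(pop), fit$mu_pop, fit$sigma_pop)
  eta <- alpha[pop] + fit$beta_prey * dataset$prey +
    fit$beta_bodysize * dataset$bodysize
  out <- dataset
  if (spec$family == "beta_binomial") {
    out$hatched <- betabinom_sample(dataset$clutch,
                                    pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12),
                                    fit$phi)
  } else {
    if (spec$olre && fit$sigma_eps > 0)
      eta <- eta + rnorm(length(eta), 0, fit$sigma_eps)
    out$hatched <- rbinom(length(eta), dataset$clutch, plogis(eta))
  }
  out
}

#' Parametric-bootstrap confidence interval for the dispersion statistic
#'
#' Simulates `n_boot` datasets from the fitted model, refits the same model
#' family to each, recomputes the Pearson dispersion statistic, and returns
#' the observed point estimate together with the 2.5/97.5 percentiles of the
#' bootstrap distribution. Non-convergent bootstrap refits are dropped from
#' the percentiles and counted; if more than 20% fail a warning is recorded
#' in the report.
#'
#' @inheritParams pearson_dispersion
#' @param n_boot number of bootstrap replicates (`>= 100`; default 1000).
#' @param seed optional integer seed.
#' @return list of class `dispersion_report` with elements `point`,
#'   `boot_lo`, `boot_hi`, `n_boot`, `residual_df`, `n_failed`, `warning`.
#' @export
bootstrap_dispersion_ci <- function(dataset, fit, n_boot = 1000,
                                    control = glmm_control(), seed = NULL) {
  if (n_boot < 100) stop("'n_boot' must be >= 100")
  dataset <- validate_dataset(as.data.frame(dataset))
  if (!is.null(seed)) set.seed(seed)
  obs <- pearson_dispersion(dataset, fit, control)
  stats <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    db <- simulate_from_fit(dataset, fit)
    fb <- fit_ml(db, fit$spec, control)
    if (fb$converged)
      stats[b] <- tryCatch(pearson_dispersion(db, fb, control)$point,
                           error = function(e) NA_real_)
  }
  ok <- stats[!is.na(stats)]
  n_failed <- n_boot - length(ok)
  qs <- quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(list(point = obs$point, boot_lo = qs[1L], boot_hi = qs[2L],
                 n_boot = n_boot, residual_df = obs$residual_df,
                 n_failed = n_failed,
                 warning = if (n_failed > 0.2 * n_boot)
                   "more than 20% of bootstrap refits failed to converge"
                 else NULL),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("Pearson dispersion %.3f (df = %d), bootstrap 95%% CI [%.3f, %.3f]\n",
              x$point, x$residual_df, x$boot_lo, x$boot_hi))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}
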