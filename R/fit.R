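# Bayesian estimation of the constrained speed-accuracy LBA model.

# Expand a variant theta matrix (6 columns) to the full 8-column layout by
# deriving the distractor drifts from the drift-sum constraint.
.expand_variant_theta <- function(theta, drift_sum) {
  cbind(theta[, 1L], theta[, 2L], theta[, 3L],
        drift_sum - theta[, 3L], theta[, 4L],
        drift_sum - theta[, 4L], theta[, 5L], theta[, 6L])
}

# Build a sat_parameters object from a free-parameter vector.
.theta_to_params <- function(theta, variant = "main", drift_sum = 1,
                             A = 0, b_ratio = 1.2) {
  if (variant == "over_constrained")
    theta <- as.vector(.expand_variant_theta(matrix(theta, nrow = 1L),
                                             drift_sum))
  sat_parameters(t0 = theta[1], b_acc = theta[2],
                 v_t_acc = theta[3], v_d_acc = theta[4],
                 v_t_spd = theta[5], v_d_spd = theta[6],
                 s_acc = theta[7], p = theta[8],
                 A = A, b_ratio = b_ratio)
}

#' Log posterior of the speed-accuracy model
#'
#' `dataset_loglik(params, trials) + sum(log prior densities)`; returns
#' `-Inf` for parameters outside the prior support.
#'
#' @param params A [sat_parameters()] object.
#' @param trials A trial table.
#' @param priors A named prior list as from [sat_priors()].
#' @param density_floor Passed to [dataset_loglik()].
#' @return A scalar log posterior.
#' @export
sat_log_posterior <- function(params, trials, priors = sat_priors(),
                              density_floor = 1e-29) {
  stopifnot(inherits(params, "sat_parameters"))
  theta <- .params_to_theta(params)[match(names(priors),
                                          sat_free_parameter_names())]
  lp <- prior_log_density(priors, theta)
  if (!is.finite(lp)) return(-Inf)
  lp + dataset_loglik(params, trials, density_floor = density_floor)
}

#' Fit the speed-accuracy LBA model by DE-MCMC
#'
#' Chains are initialized from the priors (overdispersed relative to the
#' posterior, so [rhat()] can detect non-convergence) and run with
#' differential-evolution proposals; the likelihood is evaluated in
#' compiled code for all chains at once.
#'
#' @param trials Trial table (columns `condition`, `response`, `rt`).
#' @param priors Named prior list; defaults to [sat_priors()] for the
#'   chosen variant.
#' @param variant `"main"` (8 free parameters including `p`) or
#'   `"over_constrained"` (drift sums fixed; negative control).
#' @param n_chains Number of chains; default 3 per free parameter.
#' @param n_iter,burn_in Sampler length; defaults 5000 with half burn-in.
#' @param A,b_ratio Fixed model constants.
#' @param drift_sum Drift-sum constant of the over-constrained variant.
#' @param density_floor Per-trial likelihood floor.
#' @param seed Optional seed.
#' @param ... Further arguments passed to [run_demc()].
#' @return A list of class `sat_fit` with elements `posterior`
#'   (a `posterior_samples` object), `priors`, `variant`, constants and
#'   the trial counts.
#' @export
fit_sat <- function(trials, priors = NULL,
                    variant = c("main", "over_constrained"),
                    n_chains = NULL, n_iter = 5000, burn_in = floor(n_iter / 2),
                    A = 0, b_ratio = 1.2, drift_sum = 1,
                    density_floor = 1e-29, seed = NULL, ...) {
  variant <- match.arg(variant)
  priors <- priors %||% sat_priors(variant)
  prep <- .prepare_trials(trials)
  d <- length(priors)
  n_chains <- n_chains %||% (3L * d)

  log_post <- function(theta) {
    if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1L)
    lp <- prior_log_density(priors, theta)
    ok <- which(is.finite(lp))
    if (length(ok)) {
      full <- if (variant == "over_constrained")
        .expand_variant_theta(theta[ok, , drop = FALSE], drift_sum)
      else theta[ok, , drop = FALSE]
      lp[ok] <- lp[ok] + sat_loglik_cpp(full, prep$is_acc, prep$resp, prep$rt,
                                        A, b_ratio, density_floor)
    }
    lp
  }

  post <- run_demc(log_post,
                   init = function(n) prior_sample(priors, n),
                   n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                   seed = seed, param_names = names(priors), ...)
  structure(list(posterior = post, priors = priors, variant = variant,
                 A = A, b_ratio = b_ratio, drift_sum = drift_sum,
                 density_floor = density_floor,
                 n_trials = nrow(trials),
                 condition_counts = table(trials$condition),
                 seed = seed),
            class = "sat_fit")
}

#' @export
print.sat_fit <- function(x, ...) {
  cat("Speed-accuracy LBA fit (", x$variant, " model, ",
      x$n_trials, " trials)\n", sep = "")
  print(x$posterior)
  print(posterior_summary(x$posterior), digits = 4)
  invisible(x)
}

#' Parameters at the posterior mode of a fit
#'
#' Returns the stored draw with the highest log posterior, as a
#' [sat_parameters()] object — used e.g. to compare fit quality between
#' the main and over-constrained models via [dataset_loglik()].
#'
#' @param fit A `sat_fit` object.
#' @return A [sat_parameters()] object.
#' @export
sat_posterior_mode <- function(fit) {
  stopifnot(inherits(fit, "sat_fit"))
  post <- fit$posterior
  keep <- seq.int(post$burn_in + 1L, post$n_iter)
  lp <- post$log_posterior[, keep, drop = FALSE]
  best <- arrayInd(which.max(lp), dim(lp))
  theta <- post$samples[best[1L], keep[best[2L]], ]
  .theta_to_params(theta, fit$variant, fit$drift_sum, fit$A, fit$b_ratio)
}

#' Posterior-mean parameters of a fit
#'
#' @param fit A `sat_fit` object.
#' @return A [sat_parameters()] object at the marginal posterior means.
#' @export
sat_posterior_mean <- function(fit) {
  stopifnot(inherits(fit, "sat_fit"))
  .theta_to_params(colMeans(posterior_draws(fit$posterior)),
                   fit$variant, fit$drift_sum, fit$A, fit$b_ratio)
}
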