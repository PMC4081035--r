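# Prior specifications: small data structures with evaluable log densities
# and samplers, used both for posterior evaluation and chain initialization.

#' Prior building blocks
#'
#' `prior_uniform()` and `prior_truncnorm()` build per-parameter prior
#' specifications; a named list of them forms the model's `PriorSpec`.
#'
#' @param lower,upper Support bounds.
#' @param mean,sd Location and scale of the (truncated) normal.
#' @return A list of class `prior_spec`.
#' @export
prior_uniform <- function(lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), upper > lower)
  structure(list(family = "uniform", lower = lower, upper = upper),
            class = "prior_spec")
}

#' @rdname prior_uniform
#' @export
prior_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, upper > lower)
  structure(list(family = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "prior_spec")
}

.prior_logd_one <- function(spec, x) {
  out <- rep(-Inf, length(x))
  inside <- x >= spec$lower & x <= spec$upper
  if (spec$family == "uniform") {
    out[inside] <- -log(spec$upper - spec$lower)
  } else {
    mass <- pnorm(spec$upper, spec$mean, spec$sd) -
            pnorm(spec$lower, spec$mean, spec$sd)
    out[inside] <- dnorm(x[inside], spec$mean, spec$sd, log = TRUE) - log(mass)
  }
  out
}

.prior_sample_one <- function(spec, n) {
  if (spec$family == "uniform") return(runif(n, spec$lower, spec$upper))
  # inverse-CDF sampling of the truncated normal
  plo <- pnorm(spec$lower, spec$mean, spec$sd)
  phi <- pnorm(spec$upper, spec$mean, spec$sd)
  qnorm(runif(n, plo, phi), spec$mean, spec$sd)
}

#' Default priors for the speed-accuracy LBA model
#'
#' Weakly informative on the evidence scale pinned by the speed-setting
#' drift SD of 1: `t0 ~ U(0, 0.5)` seconds; thresholds and the
#' accuracy-setting drift SD `~ Normal(0.5, 0.5^2)` truncated to `(0, Inf)`;
#' all mean drift rates `~ Normal(1, 2^2)` truncated to `(-3, 8)`;
#' `p ~ U(0, 1)`. The over-constrained variant drops the two distractor
#' drift parameters (they are derived from the drift-sum constraint).
#'
#' @param variant `"main"` or `"over_constrained"`.
#' @return A named list of `prior_spec` objects, one per free parameter.
#' @export
sat_priors <- function(variant = c("main", "over_constrained")) {
  variant <- match.arg(variant)
  drift <- prior_truncnorm(1, 2, lower = -3, upper = 8)
  pr <- list(
    t0 = prior_uniform(0, 0.5),
    b_acc = prior_truncnorm(0.5, 0.5, lower = 0),
    v_t_acc = drift,
    v_d_acc = drift,
    v_t_spd = drift,
    v_d_spd = drift,
    s_acc = prior_truncnorm(0.5, 0.5, lower = 0),
    p = prior_uniform(0, 1))
  if (variant == "over_constrained")
    pr <- pr[c("t0", "b_acc", "v_t_acc", "v_t_spd", "s_acc", "p")]
  pr
}

#' Joint prior log density
#'
#' @param priors Named list of `prior_spec` objects.
#' @param theta Numeric vector (one point) or matrix (rows are points);
#'   columns follow the order of `priors`.
#' @return Log densities, `-Inf` outside the support.
#' @export
prior_log_density <- function(priors, theta) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1L)
  stopifnot(ncol(theta) == length(priors))
  out <- numeric(nrow(theta))
  for (j in seq_along(priors))
    out <- out + .prior_logd_one(priors[[j]], theta[, j])
  out
}

#' Sample parameter vectors from the prior
#'
#' @inheritParams prior_log_density
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return An `n` by `length(priors)` matrix with named columns.
#' @export
prior_sample <- function(priors, n, seed = NULL) {
  with_seed(seed, {
    out <- vapply(priors, .prior_sample_one, numeric(n), n = n)
    if (n == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(priors)))
    out
  })
}
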