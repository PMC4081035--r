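# Differential-evolution MCMC: proposals for chain i are
# x_i + gamma * (x_j - x_k) + jitter with j != k != i drawn from the other
# chains, Metropolis-accepted. Efficient for the correlated posteriors
# typical of accumulator-model likelihoods.

#' Run a differential-evolution MCMC sampler
#'
#' All chains are updated per iteration using the previous generation's
#' states as the proposal pool. The scale `gamma` defaults to the standard
#' `2.38 / sqrt(2 d)`, with a fraction `gamma1_prob` of proposals made at
#' `gamma = 1` to allow jumps between modes; a small uniform jitter keeps
#' proposals off the difference lattice.
#'
#' @param log_post Log target density. Must accept a matrix (rows are
#'   parameter vectors) and return one value per row; `-Inf` marks points
#'   outside the support.
#' @param init Either an `n_chains` by `d` matrix of starting points or a
#'   function `f(n)` returning such a matrix (e.g. prior draws). Starting
#'   points with non-finite log posterior are redrawn (only possible with
#'   a function `init`).
#' @param n_iter Total iterations stored per chain.
#' @param burn_in Number of initial iterations flagged as burn-in.
#' @param n_chains Number of interacting chains (`>= 4`); a common choice
#'   is 3 times the number of parameters.
#' @param gamma Proposal scale; default `2.38 / sqrt(2 d)`.
#' @param gamma1_prob Fraction of proposals made at `gamma = 1`.
#' @param jitter Half-width of the per-coordinate uniform jitter.
#' @param seed Optional seed for full reproducibility.
#' @param param_names Optional column names for the samples.
#' @param stuck_window If no chain accepts any proposal over this many
#'   consecutive iterations, sampling aborts with a diagnostic error.
#' @param outlier_correct During burn-in only, periodically reset chains
#'   whose mean log posterior over the recent half of their history falls
#'   far below the chain population's median (more than four upper
#'   half-spreads, floored at `5 sqrt(d)`) to the current best chain's
#'   state.
#'   Difference-based proposals shrink as the population converges, so a
#'   chain stranded on a low-density ridge can otherwise stay there
#'   indefinitely; the reset touches only discarded iterations, leaving
#'   the retained sample a valid DE-MCMC draw.
#' @param outlier_every Iteration interval of the outlier check.
#' @return An object of class `posterior_samples`: a list with the sample
#'   array (`chains x iterations x parameters`), the log-posterior matrix,
#'   per-chain acceptance rates and the burn-in index.
#' @examples
#' lp <- function(x) -0.5 * rowSums(x^2)
#' fit <- run_demc(lp, init = function(n) matrix(rnorm(2 * n), n),
#'                 n_iter = 500, burn_in = 250, n_chains = 8, seed = 1)
#' posterior_summary(fit)
#' @export
run_demc <- function(log_post, init, n_iter, burn_in, n_chains = NULL,
                     gamma = NULL, gamma1_prob = 0.1, jitter = 0.001,
                     seed = NULL, param_names = NULL, stuck_window = 500L,
                     outlier_correct = TRUE, outlier_every = 100L) {
  if (is.matrix(init)) {
    n_chains <- n_chains %||% nrow(init)
    if (nrow(init) != n_chains)
      stop("`init` matrix must have `n_chains` rows", call. = FALSE)
  } else if (!is.function(init)) {
    stop("`init` must be a matrix or a function", call. = FALSE)
  }
  if (is.null(n_chains)) stop("`n_chains` required with a function `init`",
                              call. = FALSE)
  n_chains <- as.integer(n_chains)
  if (n_chains < 4L) stop("`n_chains` must be at least 4", call. = FALSE)
  if (n_iter <= burn_in) stop("`n_iter` must exceed `burn_in`", call. = FALSE)

  with_seed(seed, {
    X <- if (is.matrix(init)) init else init(n_chains)
    d <- ncol(X)
    gamma <- gamma %||% (2.38 / sqrt(2 * d))
    lp_cur <- log_post(X)
    tries <- 0L
    while (any(!is.finite(lp_cur))) {
      tries <- tries + 1L
      if (tries > 200L || is.matrix(init))
        stop("could not initialize all chains at finite log posterior",
             call. = FALSE)
      bad <- which(!is.finite(lp_cur))
      X[bad, ] <- init(length(bad))
      lp_cur[bad] <- log_post(X[bad, , drop = FALSE])
    }

    samples <- array(NA_real_, c(n_chains, n_iter, d))
    lp_store <- matrix(NA_real_, n_chains, n_iter)
    n_accept <- integer(n_chains)
    recent <- integer(0)
    idx <- seq_len(n_chains)

    for (it in seq_len(n_iter)) {
      g <- ifelse(runif(n_chains) < gamma1_prob, 1, gamma)
      jk <- vapply(idx, function(i) sample(idx[-i], 2L), integer(2L))
      prop <- X + g * (X[jk[1L, ], , drop = FALSE] -
                       X[jk[2L, ], , drop = FALSE]) +
              matrix(runif(n_chains * d, -jitter, jitter), n_chains, d)
      lp_prop <- log_post(prop)
      accept <- log(runif(n_chains)) < lp_prop - lp_cur
      accept[!is.finite(lp_prop)] <- FALSE
      if (any(accept)) {
        X[accept, ] <- prop[accept, , drop = FALSE]
        lp_cur[accept] <- lp_prop[accept]
      }
      n_accept <- n_accept + accept
      if (outlier_correct && it <= burn_in && it >= outlier_every &&
          it %% outlier_every == 0L) {
        window <- seq.int(max(1L, it %/% 2L), it - 1L)
        mlp <- rowMeans(cbind(lp_store[, window, drop = FALSE], lp_cur))
        # reference the upper half-spread: stranded chains sit below the
        # median and cannot inflate it, so the rule still fires when more
        # than a quarter of the population is stranded
        qs <- quantile(mlp, c(0.5, 0.75), names = FALSE)
        bad <- which(mlp < qs[1L] - max(4 * (qs[2L] - qs[1L]), 5 * sqrt(d)))
        if (length(bad)) {
          best <- which.max(lp_cur)
          X[bad, ] <- matrix(X[best, ], length(bad), d, byrow = TRUE)
          lp_cur[bad] <- lp_cur[best]
        }
      }
      samples[, it, ] <- X
      lp_store[, it] <- lp_cur
      recent <- c(recent, sum(accept))
      if (length(recent) > stuck_window) recent <- recent[-1L]
      if (length(recent) == stuck_window && sum(recent) == 0L)
        stop("all chains stuck: no acceptances in the last ", stuck_window,
             " iterations; check the target density and proposal scale",
             call. = FALSE)
    }
    if (!is.null(param_names)) dimnames(samples)[[3]] <- param_names
    structure(list(samples = samples, log_posterior = lp_store,
                   accept_rate = n_accept / n_iter, burn_in = as.integer(burn_in),
                   n_chains = n_chains, n_iter = as.integer(n_iter), d = d,
                   param_names = param_names, gamma = gamma, seed = seed),
              class = "posterior_samples")
  })
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d chains x %d iterations x %d parameters\n",
              x$n_chains, x$n_iter, x$d))
  cat(sprintf("  burn-in %d; acceptance rate %.2f (mean across chains)\n",
              x$burn_in, mean(x$accept_rate)))
  invisible(x)
}

#' Pooled post-burn-in draws
#'
#' @param x A `posterior_samples` object.
#' @param include_burn_in Keep the burn-in iterations too?
#' @return A matrix, one row per retained chain-iteration, named columns.
#' @export
posterior_draws <- function(x, include_burn_in = FALSE) {
  stopifnot(inherits(x, "posterior_samples"))
  keep <- if (include_burn_in) seq_len(x$n_iter)
          else seq.int(x$burn_in + 1L, x$n_iter)
  out <- apply(x$samples[, keep, , drop = FALSE], 3L, as.vector)
  if (!is.matrix(out)) out <- matrix(out, ncol = x$d)
  colnames(out) <- x$param_names
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat per parameter: with `m` chains of length `n`,
#' within-chain variance `W`, between-chain variance `B = n var(means)`,
#' `R-hat = sqrt(((n-1)/n W + B/n) / W)`. Values near 1 indicate the
#' chains have mixed.
#'
#' @param x A `posterior_samples` object (post-burn-in iterations used) or
#'   a 3-d array `chains x iterations x parameters`.
#' @return A named numeric vector, one value per parameter.
#' @export
rhat <- function(x) {
  if (inherits(x, "posterior_samples")) {
    arr <- x$samples[, seq.int(x$burn_in + 1L, x$n_iter), , drop = FALSE]
    if (!is.null(x$param_names)) dimnames(arr)[[3]] <- x$param_names
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else {
    stop("`x` must be a posterior_samples object or a 3-d array",
         call. = FALSE)
  }
  m <- dim(arr)[1]; n <- dim(arr)[2]; d <- dim(arr)[3]
  if (m < 2L) stop("R-hat requires at least 2 chains", call. = FALSE)
  out <- numeric(d)
  for (j in seq_len(d)) {
    ch <- arr[, , j, drop = FALSE]
    means <- rowMeans(ch[, , 1])
    W <- mean(apply(ch[, , 1], 1L, var))
    B <- n * var(means)
    out[j] <- if (W == 0) { if (B == 0) 1 else Inf }
              else sqrt(((n - 1) / n * W + B / n) / W)
  }
  names(out) <- dimnames(arr)[[3]]
  out
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, median and central 95\% interval from the
#' pooled post-burn-in draws.
#'
#' @param x A `posterior_samples` object.
#' @return A data frame with columns `parameter`, `mean`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(x) {
  draws <- posterior_draws(x)
  qs <- apply(draws, 2L, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
             mean = colMeans(draws),
             median = qs[2L, ],
             lower = qs[1L, ],
             upper = qs[3L, ],
             row.names = NULL)
}
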