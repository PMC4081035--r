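# Closed-form LBA first-passage mathematics and simulation.
#
# Internal scalar-parameter, vector-t kernels; the exported wrappers
# validate inputs and unpack accumulator objects. For A > 0 the standard
# LBA closed form (difference of scaled Gaussian cdf/pdf terms) is used;
# for A = 0 the analytic limit: the crossing time is b / drift with
# drift ~ N(v, s), so pdf(t) = b / (s t^2) * phi((b/t - v)/s) and
# F(t) = Phi((v - b/t)/s).

.fpt_pdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tt <- t[pos]
  if (A <= 0) {
    out[pos] <- b / (tt^2 * s) * dnorm((b / tt - v) / s)
  } else {
    ts <- tt * s
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    d <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A
    out[pos] <- pmax(d, 0)
  }
  out
}

.fpt_cdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tt <- t[pos]
  if (A <= 0) {
    out[pos] <- pnorm((v - b / tt) / s)
  } else {
    ts <- tt * s
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    F <- 1 + (b - A - tt * v) / A * pnorm(z1) -
             (b - tt * v) / A * pnorm(z2) +
             ts / A * (dnorm(z1) - dnorm(z2))
    out[pos] <- pmin(pmax(F, 0), 1)
  }
  # crossing at t = Inf never happens in finite time but the limit exists
  out[is.infinite(t) & t > 0] <- pnorm(v / s)
  out
}

.check_t <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || anyNA(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
}

#' First-passage time density of one accumulator
#'
#' Density of the threshold-crossing (decision) time of a single
#' accumulator, excluding non-decision time. The density is defective when
#' negative drift draws are possible: it integrates to `pnorm(v/s)`, the
#' probability that the accumulator ever finishes.
#'
#' @param acc An [accumulator()] object.
#' @param t Decision times in seconds (finite, `> 0`).
#' @return Densities (1/seconds), same length as `t`.
#' @examples
#' acc <- accumulator(b = 0.24, v = 0.66, s = 0.10)
#' integrate(function(t) lba_fpt_pdf(acc, t), 0, Inf)$value  # ~ pnorm(6.6)
#' @export
lba_fpt_pdf <- function(acc, t) {
  stopifnot(inherits(acc, "lba_accumulator"))
  .check_t(t)
  if (any(t <= 0)) stop("decision times `t` must be positive", call. = FALSE)
  .fpt_pdf(t, acc$b, acc$A, acc$v, acc$s)
}

#' First-passage time distribution function of one accumulator
#'
#' `P(crossing time <= t)`; nondecreasing in `t` with limit `pnorm(v/s)`
#' (the accumulator's finish probability) as `t -> Inf`.
#'
#' @inheritParams lba_fpt_pdf
#' @return Probabilities, same length as `t`.
#' @export
lba_fpt_cdf <- function(acc, t) {
  stopifnot(inherits(acc, "lba_accumulator"))
  .check_t(t)
  if (any(t <= 0)) stop("decision times `t` must be positive", call. = FALSE)
  .fpt_cdf(t, acc$b, acc$A, acc$v, acc$s)
}

.race_parts <- function(race, winner) {
  winner <- match.arg(winner, c("target", "distractor"))
  if (winner == "target") list(w = race$target, l = race$distractor)
  else list(w = race$distractor, l = race$target)
}

#' Defective density of (response, RT) for a two-accumulator race
#'
#' Density that the requested accumulator wins at observed response time
#' `t`: `f_winner(t - t0) * (1 - F_loser(t - t0))`, renormalized by the
#' race's finish probability (see [race_finish_prob()]) so the two
#' defective densities together integrate to 1. Returns 0 (not an error)
#' for `t <= t0`.
#'
#' @param race A [race_spec()] object.
#' @param winner `"target"` or `"distractor"`.
#' @param t Observed response times in seconds (decision time plus `t0`).
#' @return Nonnegative densities, same length as `t`.
#' @export
lba_defective_pdf <- function(race, winner = c("target", "distractor"), t) {
  stopifnot(inherits(race, "lba_race"))
  .check_t(t)
  pr <- .race_parts(race, winner)
  tau <- t - race$t0
  Z <- race_finish_prob(race)
  pmax(.fpt_pdf(tau, pr$w$b, pr$w$A, pr$w$v, pr$w$s) *
         (1 - .fpt_cdf(tau, pr$l$b, pr$l$A, pr$l$v, pr$l$s)) / Z, 0)
}

#' Distribution function of the race's response time
#'
#' `P(RT <= t | race finishes)`: probability that at least one accumulator
#' has crossed by decision time `t - t0`, renormalized by the finish
#' probability. Used for analytic/simulation agreement checks.
#'
#' @inheritParams lba_defective_pdf
#' @return Probabilities, same length as `t`.
#' @export
lba_race_cdf <- function(race, t) {
  stopifnot(inherits(race, "lba_race"))
  .check_t(t)
  tau <- t - race$t0
  Z <- race_finish_prob(race)
  St <- 1 - .fpt_cdf(tau, race$target$b, race$target$A,
                     race$target$v, race$target$s)
  Sd <- 1 - .fpt_cdf(tau, race$distractor$b, race$distractor$A,
                     race$distractor$v, race$distractor$s)
  pmin(pmax((1 - St * Sd) / Z, 0), 1)
}

#' Choice probability of a race
#'
#' Numerical integral of the renormalized defective density over all
#' response times; the target and distractor probabilities sum to 1.
#'
#' @inheritParams lba_defective_pdf
#' @return A single probability.
#' @examples
#' race <- race_spec(accumulator(b = 0.42, v = 1.16, s = 0.28),
#'                   accumulator(b = 0.42, v = 0.81, s = 0.28), t0 = 0.09)
#' lba_choice_prob(race, "target")
#' @export
lba_choice_prob <- function(race, winner = c("target", "distractor")) {
  stopifnot(inherits(race, "lba_race"))
  winner <- match.arg(winner)
  w <- .race_parts(race, winner)$w
  # piecewise adaptive quadrature: a sharply peaked winner density (small
  # s) can be missed entirely by one pass over the unbounded interval, so
  # split at crossing times bracketing the density's bulk (b / (v +- 3s))
  cuts <- race$t0 + w$b / sort(c(abs(w$v) + 3 * w$s,
                                 max(w$v - 3 * w$s, (abs(w$v) + 3 * w$s) / 50)),
                               decreasing = TRUE)
  bounds <- unique(c(race$t0, cuts, Inf))
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    res <- tryCatch(
      integrate(function(t) lba_defective_pdf(race, winner, t),
                lower = bounds[i], upper = bounds[i + 1L],
                rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 1000L),
      error = function(e) e)
    if (inherits(res, "error"))
      stop("choice-probability integration failed on (", bounds[i], ", ",
           bounds[i + 1L], "): ", conditionMessage(res),
           "\n  race: t0=", race$t0,
           " target(b=", race$target$b, ",v=", race$target$v, ")",
           " distractor(b=", race$distractor$b, ",v=", race$distractor$v, ")",
           call. = FALSE)
    total <- total + res$value
  }
  min(max(total, 0), 1)
}

# Vectorized raw race draw: start points, drifts, crossing times.
# Crossing time is (b - start) / drift for positive drifts, Inf otherwise.
.draw_race <- function(race, n) {
  tg <- race$target; ds <- race$distractor
  start_t <- if (tg$A > 0) runif(n, 0, tg$A) else numeric(n)
  start_d <- if (ds$A > 0) runif(n, 0, ds$A) else numeric(n)
  drift_t <- rnorm(n, tg$v, tg$s)
  drift_d <- rnorm(n, ds$v, ds$s)
  ct_t <- ifelse(drift_t > 0, (tg$b - start_t) / drift_t, Inf)
  ct_d <- ifelse(drift_d > 0, (ds$b - start_d) / drift_d, Inf)
  list(start_t = start_t, drift_t = drift_t, ct_t = ct_t,
       start_d = start_d, drift_d = drift_d, ct_d = ct_d)
}

#' Simulate trials from a race
#'
#' Draws per-trial start points and drift rates independently for the two
#' accumulators; the response is whichever crosses first and the RT is its
#' crossing time plus `t0`. Trials in which neither accumulator finishes
#' (both drift draws non-positive) are redrawn, matching the renormalized
#' likelihood; an error is raised if redrawing fails within
#' `max_attempts` total redraws.
#'
#' @inheritParams lba_defective_pdf
#' @param n Number of trials (`>= 1`).
#' @param seed Optional integer seed; when given the output is fully
#'   reproducible and the caller's RNG state is untouched.
#' @param max_attempts Cap on total redraws of non-terminating trials.
#' @return A data frame with columns `winner` (`"target"`/`"distractor"`)
#'   and `rt` (seconds).
#' @export
lba_simulate_trials <- function(race, n, seed = NULL, max_attempts = 1e6) {
  stopifnot(inherits(race, "lba_race"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    d <- .draw_race(race, n)
    ct_t <- d$ct_t; ct_d <- d$ct_d
    attempts <- 0L
    repeat {
      bad <- which(!is.finite(pmin(ct_t, ct_d)))
      if (length(bad) == 0L) break
      attempts <- attempts + length(bad)
      if (attempts > max_attempts)
        stop("race finish probability ~0: exceeded ", max_attempts,
             " redraws of non-terminating trials", call. = FALSE)
      rd <- .draw_race(race, length(bad))
      ct_t[bad] <- rd$ct_t
      ct_d[bad] <- rd$ct_d
    }
    data.frame(
      winner = ifelse(ct_t <= ct_d, "target", "distractor"),
      rt = pmin(ct_t, ct_d) + race$t0,
      stringsAsFactors = FALSE)
  })
}

#' Simulate target-accumulator evidence trajectories
#'
#' Simulates race trials and returns the linear evidence paths of the
#' *target* accumulator for trials where the requested winner won (the
#' default, `"target"`, corresponds to correct decisions). Each path is
#' `evidence(t) = start + drift * t` on a grid of step `dt`, truncated at
#' the accumulator's own crossing time, with the exact crossing point
#' `(crossing_time, b)` appended so every path terminates at threshold.
#' For `winner_filter = "distractor"` the target accumulator need not
#' cross; its path is then truncated at the trial's decision time.
#'
#' @inheritParams lba_simulate_trials
#' @param dt Grid step in seconds (`> 0`).
#' @param winner_filter Keep only trials won by this accumulator.
#' @return A list of class `trajectory_set`; each element has fields
#'   `start`, `drift`, `crossing_time` and `path` (a data frame of
#'   `time`, `evidence`).
#' @export
lba_simulate_trajectories <- function(race, n, dt = 0.001,
                                      winner_filter = c("target", "distractor"),
                                      seed = NULL, max_attempts = 1e6) {
  stopifnot(inherits(race, "lba_race"))
  winner_filter <- match.arg(winner_filter)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    kept <- list(); total <- 0L
    while (length(kept) < n) {
      batch <- max(4L * (n - length(kept)), 64L)
      total <- total + batch
      if (total > max_attempts)
        stop("winner filter \"", winner_filter, "\" never satisfied within ",
             max_attempts, " simulated trials", call. = FALSE)
      d <- .draw_race(race, batch)
      finished <- is.finite(pmin(d$ct_t, d$ct_d))
      won <- if (winner_filter == "target") d$ct_t <= d$ct_d else d$ct_d < d$ct_t
      sel <- which(finished & won)
      for (i in sel) {
        if (length(kept) >= n) break
        end_t <- if (winner_filter == "target") d$ct_t[i] else d$ct_d[i]
        grid <- seq(0, end_t, by = dt)
        ev <- d$start_t[i] + d$drift_t[i] * grid
        if (winner_filter == "target" && grid[length(grid)] < end_t) {
          grid <- c(grid, end_t)
          ev <- c(ev, race$target$b)
        }
        kept[[length(kept) + 1L]] <- structure(
          list(start = d$start_t[i], drift = d$drift_t[i],
               crossing_time = if (winner_filter == "target") d$ct_t[i] else NA_real_,
               path = data.frame(time = grid, evidence = ev)),
          class = "trajectory_sample")
      }
    }
    structure(kept, class = "trajectory_set",
              threshold = race$target$b, winner_filter = winner_filter)
  })
}
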