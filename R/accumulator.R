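#' Single linear ballistic accumulator
#'
#' One racer in an LBA decision: evidence starts at a point drawn uniformly
#' on `[0, A]` and grows exactly linearly at a drift rate drawn once per
#' trial from `Normal(v, s)`, until it reaches the threshold `b`. All
#' variability is between trials; within a trial the path is ballistic
#' (noise free).
#'
#' @param b Evidence threshold (arbitrary evidence units, `> 0`).
#' @param A Upper bound of the uniform start-point distribution
#'   (evidence units, `>= 0`, `< b`). The default `0` is the ballistic
#'   limit in which the crossing time is simply `b` divided by the trial's
#'   drift draw; the package uses this limit throughout unless told
#'   otherwise.
#' @param v Mean drift rate (evidence units per second).
#' @param s Between-trial standard deviation of the drift rate
#'   (evidence units per second, `> 0`).
#'
#' @return An object of class `lba_accumulator`.
#' @examples
#' acc <- accumulator(b = 0.24, v = 0.66, s = 0.10)
#' lba_fpt_pdf(acc, c(0.3, 0.4, 0.5))
#' @export
accumulator <- function(b, A = 0, v, s) {
  for (nm in c("b", "A", "v", "s")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  if (b <= 0) stop("threshold `b` must be positive", call. = FALSE)
  if (A < 0) stop("start-point range `A` must be non-negative", call. = FALSE)
  if (A >= b) stop("start-point range `A` must be below the threshold `b`",
                   call. = FALSE)
  if (s <= 0) stop("drift-rate SD `s` must be positive", call. = FALSE)
  structure(list(b = b, A = A, v = v, s = s), class = "lba_accumulator")
}

#' @export
print.lba_accumulator <- function(x, ...) {
  cat(sprintf("LBA accumulator: b = %g, A = %g, v = %g, s = %g\n",
              x$b, x$A, x$v, x$s))
  invisible(x)
}

#' Two-accumulator race specification
#'
#' The generative object for one trial: a target and a distractor
#' accumulator race to threshold, and the first to cross triggers the
#' response. The observed response time is the winning crossing time plus
#' the non-decision time `t0` (perceptual encoding and motor execution).
#'
#' @param target,distractor [accumulator()] objects.
#' @param t0 Non-decision time in seconds (`>= 0`).
#'
#' @return An object of class `lba_race`.
#' @seealso [lba_defective_pdf()], [lba_simulate_trials()]
#' @examples
#' race_spec(accumulator(b = 0.29, v = 2.30, s = 1),
#'           accumulator(b = 0.29, v = 1.41, s = 1), t0 = 0.10)
#' @export
race_spec <- function(target, distractor, t0 = 0) {
  if (!inherits(target, "lba_accumulator") ||
      !inherits(distractor, "lba_accumulator"))
    stop("`target` and `distractor` must be `lba_accumulator` objects",
         call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("`t0` must be a single non-negative number", call. = FALSE)
  race <- structure(list(target = target, distractor = distractor, t0 = t0),
                    class = "lba_race")
  if (race_finish_prob(race) <= 1e-12)
    stop("race has finish probability ~0: both drift means are far negative",
         call. = FALSE)
  race
}

#' @export
print.lba_race <- function(x, ...) {
  cat("LBA race (t0 =", x$t0, "s)\n")
  cat("  target:     b =", x$target$b, " A =", x$target$A,
      " v =", x$target$v, " s =", x$target$s, "\n")
  cat("  distractor: b =", x$distractor$b, " A =", x$distractor$A,
      " v =", x$distractor$v, " s =", x$distractor$s, "\n")
  invisible(x)
}

#' Probability that a race finishes
#'
#' An accumulator crosses its threshold only when its trial drift draw is
#' positive, so a race fails to finish with probability
#' `P(drift_t <= 0) * P(drift_d <= 0)`. This finish probability is the
#' normalizing constant used by [lba_defective_pdf()], making the model a
#' proper probability distribution over terminating trials (simulation
#' redraws the rare non-terminating ones).
#'
#' @param race A [race_spec()] object.
#' @return The finish probability, in `(0, 1]`.
#' @export
race_finish_prob <- function(race) {
  stopifnot(inherits(race, "lba_race"))
  1 - pnorm(0, race$target$v, race$target$s) *
      pnorm(0, race$distractor$v, race$distractor$s)
}
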