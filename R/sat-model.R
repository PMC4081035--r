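#' Constrained speed-accuracy LBA parameter set
#'
#' The model's free parameters plus its fixed constraints. Two parameter
#' "settings" exist: an accuracy setting and a speed setting (the latter is
#' also used, unchanged, for the neutral condition). The constraints,
#' imposed by construction:
#' \itemize{
#'   \item the speed-setting threshold is `b_ratio * b_acc` (default ratio
#'     1.2, the 20\% threshold increase seen in FEF firing-rate thresholds
#'     under speed emphasis);
#'   \item the speed-setting drift-rate SD is fixed at exactly 1, pinning
#'     the model's arbitrary evidence scale (scaling property);
#'   \item the start-point range `A` is a fixed small constant shared by all
#'     accumulators (default 0, the stable ballistic limit);
#'   \item one non-decision time `t0` is shared across conditions.
#' }
#' Accuracy-emphasis trials are a mixture: with probability `p` the cue is
#' neglected and the trial is generated under the full speed setting.
#'
#' @param t0 Non-decision time in seconds (`>= 0`).
#' @param b_acc Accuracy-setting threshold (evidence units, `> 0`).
#' @param v_t_acc,v_d_acc Accuracy-setting mean drift rates for the target
#'   and distractor accumulators (evidence units/second).
#' @param v_t_spd,v_d_spd Speed-setting mean drift rates.
#' @param s_acc Accuracy-setting drift-rate SD (`> 0`).
#' @param p Cue-neglect mixture proportion in `[0, 1]`.
#' @param A Start-point range constant (`>= 0`, below both thresholds).
#' @param b_ratio Speed/accuracy threshold ratio (fixed constant).
#'
#' @return An object of class `sat_parameters`.
#' @examples
#' sat_parameters(t0 = 0.10, b_acc = 0.24, v_t_acc = 0.66, v_d_acc = 0.40,
#'                v_t_spd = 2.30, v_d_spd = 1.41, s_acc = 0.10, p = 0.08)
#' @export
sat_parameters <- function(t0, b_acc, v_t_acc, v_d_acc, v_t_spd, v_d_spd,
                           s_acc, p = 0, A = 0, b_ratio = 1.2) {
  vals <- c(t0 = t0, b_acc = b_acc, v_t_acc = v_t_acc, v_d_acc = v_d_acc,
            v_t_spd = v_t_spd, v_d_spd = v_d_spd, s_acc = s_acc, p = p,
            A = A, b_ratio = b_ratio)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    stop("all parameters must be finite numbers", call. = FALSE)
  if (t0 < 0) stop("`t0` must be non-negative", call. = FALSE)
  if (b_acc <= 0) stop("`b_acc` must be positive", call. = FALSE)
  if (s_acc <= 0) stop("`s_acc` must be positive", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (b_ratio <= 0) stop("`b_ratio` must be positive", call. = FALSE)
  if (A < 0 || A >= b_acc || A >= b_ratio * b_acc)
    stop("`A` must be non-negative and below both thresholds", call. = FALSE)
  structure(list(t0 = t0, b_acc = b_acc,
                 v_t_acc = v_t_acc, v_d_acc = v_d_acc,
                 v_t_spd = v_t_spd, v_d_spd = v_d_spd,
                 s_acc = s_acc, p = p,
                 A = A, b_ratio = b_ratio,
                 b_spd = b_ratio * b_acc, s_spd = 1),
            class = "sat_parameters")
}

#' @export
print.sat_parameters <- function(x, ...) {
  cat("Speed-accuracy LBA parameters\n")
  cat(sprintf("  shared:   t0 = %g s, p = %g, A = %g\n", x$t0, x$p, x$A))
  cat(sprintf("  accuracy: b = %g, v_t = %g, v_d = %g, s = %g\n",
              x$b_acc, x$v_t_acc, x$v_d_acc, x$s_acc))
  cat(sprintf("  speed:    b = %g (= %g x b_acc), v_t = %g, v_d = %g, s = 1\n",
              x$b_spd, x$b_ratio, x$v_t_spd, x$v_d_spd))
  invisible(x)
}

#' Published parameter presets for the two macaques
#'
#' Posterior-mean LBA estimates for the two monkeys (Q and S) of the
#' Heitz & Schall FEF speed-accuracy experiment, used throughout as
#' generating truths for synthetic data and parameter-recovery checks.
#'
#' @param monkey `"Q"` or `"S"`.
#' @return A [sat_parameters()] object.
#' @export
sat_preset <- function(monkey = c("Q", "S")) {
  monkey <- match.arg(toupper(monkey), c("Q", "S"))
  if (monkey == "Q")
    sat_parameters(t0 = 0.10, b_acc = 0.24, v_t_acc = 0.66, v_d_acc = 0.40,
                   v_t_spd = 2.30, v_d_spd = 1.41, s_acc = 0.10, p = 0.08)
  else
    sat_parameters(t0 = 0.09, b_acc = 0.42, v_t_acc = 1.16, v_d_acc = 0.81,
                   v_t_spd = 2.78, v_d_spd = 2.11, s_acc = 0.28, p = 0.12)
}

#' Names of the model's free parameters
#'
#' The core model has exactly 7 free parameters; the cue-neglect mixture
#' proportion `p` is an addition on top of the core model and is flagged
#' separately via the `"core"` attribute.
#'
#' @param core_only If `TRUE`, return only the 7 core names.
#' @return A character vector (core names followed by `"p"`), with a
#'   logical attribute `core` marking the 7 core parameters.
#' @export
sat_free_parameter_names <- function(core_only = FALSE) {
  core <- c("t0", "b_acc", "v_t_acc", "v_d_acc", "v_t_spd", "v_d_spd", "s_acc")
  if (core_only) return(core)
  structure(c(core, "p"), core = c(rep(TRUE, 7L), FALSE))
}

#' Build the race implied by one parameter setting
#'
#' @param params A [sat_parameters()] object.
#' @param setting `"speed"` (shared by the speed and neutral conditions and
#'   by cue-neglect trials) or `"accuracy"`.
#' @return A [race_spec()]: both accumulators share the setting's
#'   threshold, start-point range and drift SD.
#' @export
build_race <- function(params, setting = c("speed", "accuracy")) {
  stopifnot(inherits(params, "sat_parameters"))
  setting <- match.arg(setting)
  if (setting == "speed")
    race_spec(accumulator(params$b_spd, params$A, params$v_t_spd, params$s_spd),
              accumulator(params$b_spd, params$A, params$v_d_spd, params$s_spd),
              t0 = params$t0)
  else
    race_spec(accumulator(params$b_acc, params$A, params$v_t_acc, params$s_acc),
              accumulator(params$b_acc, params$A, params$v_d_acc, params$s_acc),
              t0 = params$t0)
}

.conditions <- c("speed", "neutral", "accuracy")
.responses <- c("target", "distractor")

#' Model density of one (condition, response, RT) cell
#'
#' Speed- and neutral-condition trials use the speed-setting defective
#' density. Accuracy-condition trials use the cue-neglect mixture:
#' `(1 - p) * accuracy-setting density + p * speed-setting density`.
#'
#' @param params A [sat_parameters()] object.
#' @param condition One of `"speed"`, `"neutral"`, `"accuracy"`.
#' @param response `"target"` or `"distractor"`.
#' @param rt Response times in seconds (vectorized).
#' @return Densities, same length as `rt`.
#' @export
trial_density <- function(params, condition, response, rt) {
  stopifnot(inherits(params, "sat_parameters"))
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% .conditions)
    stop("unknown condition label: must be one of ",
         paste(.conditions, collapse = ", "), call. = FALSE)
  response <- match.arg(response, .responses)
  spd <- lba_defective_pdf(build_race(params, "speed"), response, rt)
  if (condition != "accuracy") return(spd)
  acc <- lba_defective_pdf(build_race(params, "accuracy"), response, rt)
  (1 - params$p) * acc + params$p * spd
}

.validate_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  need <- c("condition", "response", "rt")
  if (!all(need %in% names(trials)))
    stop("`trials` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(trials$condition %in% .conditions))
    stop("`condition` values must be in {",
         paste(.conditions, collapse = ", "), "}", call. = FALSE)
  if (!all(trials$response %in% .responses))
    stop("`response` values must be in {",
         paste(.responses, collapse = ", "), "}", call. = FALSE)
  if (!is.numeric(trials$rt) || anyNA(trials$rt) || any(trials$rt <= 0))
    stop("`rt` must be positive numeric seconds", call. = FALSE)
  invisible(trials)
}

# Encode a trial table into the integer vectors used by the C++ kernel.
.prepare_trials <- function(trials) {
  .validate_trials(trials)
  list(is_acc = as.integer(trials$condition == "accuracy"),
       resp = as.integer(trials$response == "distractor"),
       rt = as.numeric(trials$rt))
}

.params_to_theta <- function(params) {
  c(params$t0, params$b_acc, params$v_t_acc, params$v_d_acc,
    params$v_t_spd, params$v_d_spd, params$s_acc, params$p)
}

#' Dataset log-likelihood of the constrained model
#'
#' Sum over trials of `log(max(trial_density, density_floor))`. The floor
#' (default `1e-29`) keeps the log-likelihood finite on pathological
#' parameter proposals (e.g. `t0` above an observed RT) without materially
#' affecting inference. Both a compiled and a plain-R evaluation path are
#' provided; they agree to near machine precision and the compiled path is
#' the sampler's hot loop.
#'
#' @param params A [sat_parameters()] object.
#' @param trials A trial table: data frame with columns `condition`,
#'   `response`, `rt` (see [read_trial_table()]).
#' @param density_floor Per-trial density floor applied before logs.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return The log-likelihood (finite scalar).
#' @export
dataset_loglik <- function(params, trials, density_floor = 1e-29,
                           engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sat_parameters"))
  engine <- match.arg(engine)
  prep <- .prepare_trials(trials)
  if (engine == "cpp") {
    return(sat_loglik_cpp(matrix(.params_to_theta(params), nrow = 1L),
                          prep$is_acc, prep$resp, prep$rt,
                          params$A, params$b_ratio, density_floor)[1L])
  }
  ll <- 0
  for (cond in unique(trials$condition)) {
    for (resp in .responses) {
      sel <- trials$condition == cond & trials$response == resp
      if (!any(sel)) next
      dens <- trial_density(params, cond, resp, trials$rt[sel])
      ll <- ll + sum(log(pmax(dens, density_floor)))
    }
  }
  ll
}

#' Over-constrained model variant
#'
#' Applies the sum-of-drift-rates form of the scaling constraint
#' (`v_t + v_d = drift_sum` within each setting) *on top of* the fixed
#' speed-setting drift SD. Either constraint alone merely pins the model's
#' arbitrary evidence scale; imposing both simultaneously removes real
#' degrees of freedom and is known to cripple the fit. The variant is kept
#' as a deliberate negative control.
#'
#' @param params A [sat_parameters()] object.
#' @param drift_sum Constrained sum of the two mean drift rates.
#' @param apply If `FALSE`, return `params` unchanged (round-trip to the
#'   main model).
#' @return A [sat_parameters()] object with `v_d_* = drift_sum - v_t_*`
#'   and attribute `variant = "over_constrained"` when applied.
#' @export
over_constrained_variant <- function(params, drift_sum = 1, apply = TRUE) {
  stopifnot(inherits(params, "sat_parameters"))
  if (!apply) return(params)
  out <- sat_parameters(t0 = params$t0, b_acc = params$b_acc,
                        v_t_acc = params$v_t_acc,
                        v_d_acc = drift_sum - params$v_t_acc,
                        v_t_spd = params$v_t_spd,
                        v_d_spd = drift_sum - params$v_t_spd,
                        s_acc = params$s_acc, p = params$p,
                        A = params$A, b_ratio = params$b_ratio)
  attr(out, "variant") <- "over_constrained"
  attr(out, "drift_sum") <- drift_sum
  out
}
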