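# Synthetic trial tables with the statistical structure the analysis
# assumes, standing in for the (undeposited) monkey behavioral data.

#' Generator configuration
#'
#' Holds the generating truth and the per-condition trial counts. The
#' defaults (2000 speed, 400 neutral, 2000 accuracy) mirror the study's
#' qualitative imbalance — the neutral condition contributed many fewer
#' trials — while keeping fits fast on one CPU.
#'
#' @param params Generating truth, a [sat_parameters()] object.
#' @param n_speed,n_neutral,n_accuracy Trial counts per condition (`>= 0`).
#' @param seed Optional integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(params, n_speed = 2000, n_neutral = 400,
                             n_accuracy = 2000, seed = NULL) {
  stopifnot(inherits(params, "sat_parameters"))
  counts <- c(n_speed = n_speed, n_neutral = n_neutral,
              n_accuracy = n_accuracy)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("trial counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("at least one trial is required", call. = FALSE)
  structure(list(params = params, n_speed = as.integer(n_speed),
                 n_neutral = as.integer(n_neutral),
                 n_accuracy = as.integer(n_accuracy), seed = seed),
            class = "generator_config")
}

#' Generate a synthetic trial table
#'
#' Speed- and neutral-condition trials are drawn from the speed-setting
#' race. Each accuracy-condition trial neglects the cue with probability
#' `p` (and is then drawn from the speed-setting race) or is drawn from
#' the accuracy-setting race. Trial order is shuffled within condition.
#' The realized per-trial neglect labels are attached as the `neglect`
#' attribute (a `trial_id`/`neglect` data frame) so recovery tests can
#' audit them without the labels ever entering the fitting path.
#'
#' @param config A [generator_config()] object.
#' @return A trial table data frame (`condition`, `response`, `rt`) with
#'   attributes `neglect` and `config`.
#' @examples
#' tab <- generate_dataset(generator_config(sat_preset("Q"), 200, 40, 200,
#'                                          seed = 1))
#' table(tab$condition)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  params <- config$params
  spd_race <- build_race(params, "speed")
  acc_race <- build_race(params, "accuracy")

  with_seed(config$seed, {
    blocks <- list()
    for (cond in c("speed", "neutral")) {
      n <- config[[paste0("n_", cond)]]
      if (n == 0L) next
      sim <- lba_simulate_trials(spd_race, n)
      sim <- sim[sample.int(n), , drop = FALSE]
      blocks[[cond]] <- data.frame(condition = cond, response = sim$winner,
                                   rt = sim$rt, stringsAsFactors = FALSE)
    }
    neglect <- NULL
    n_acc <- config$n_accuracy
    if (n_acc > 0L) {
      flags <- runif(n_acc) < params$p
      sim <- data.frame(winner = character(n_acc), rt = numeric(n_acc))
      if (any(flags)) sim[flags, ] <- lba_simulate_trials(spd_race, sum(flags))
      if (any(!flags)) sim[!flags, ] <- lba_simulate_trials(acc_race, sum(!flags))
      ord <- sample.int(n_acc)
      sim <- sim[ord, , drop = FALSE]
      flags <- flags[ord]
      blocks[["accuracy"]] <- data.frame(condition = "accuracy",
                                         response = sim$winner, rt = sim$rt,
                                         stringsAsFactors = FALSE)
      neglect <- flags
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    if (!is.null(neglect)) {
      acc_rows <- which(out$condition == "accuracy")
      attr(out, "neglect") <- data.frame(trial_id = acc_rows,
                                         neglect = neglect)
    }
    attr(out, "config") <- config
    out
  })
}

#' Realized cue-neglect fraction of a generated table
#'
#' Fraction of accuracy-condition trials that the generator drew from the
#' speed setting; its expectation is the generating `p`.
#'
#' @param trials A table from [generate_dataset()].
#' @param labels Neglect labels; defaults to the table's `neglect`
#'   attribute. A data frame with a logical/0-1 `neglect` column.
#' @return A proportion.
#' @export
neglect_fraction <- function(trials, labels = attr(trials, "neglect")) {
  if (is.null(labels))
    stop("no neglect labels: generate the table with `generate_dataset()` ",
         "or supply `labels`", call. = FALSE)
  mean(as.logical(labels$neglect))
}
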