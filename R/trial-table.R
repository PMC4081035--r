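# Trial-table I/O: the package's one observed-data format.
# Delimited text, header `condition,response,rt`; condition in
# {speed, neutral, accuracy}, response in {target, distractor}, rt in
# seconds as a decimal.

#' Read a trial table
#'
#' @param path Path to a comma-delimited file with header
#'   `condition,response,rt`.
#' @return A validated data frame of trials.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .validate_trials(tab)
  tab
}

#' Write a trial table (and optional cue-neglect sidecar)
#'
#' Numbers are written with 6 significant digits so repeated runs produce
#' byte-identical files. The optional sidecar records, for each
#' accuracy-condition trial, whether the generator neglected the accuracy
#' cue; it is kept separate so the fitting path never sees the labels.
#'
#' @param trials A trial table data frame (see [read_trial_table()]).
#' @param path Output file path.
#' @param sidecar_path Optional path for a `trial_id,neglect_flag` file;
#'   requires `trials` to carry the `neglect` attribute set by
#'   [generate_dataset()].
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path, sidecar_path = NULL) {
  .validate_trials(trials)
  out <- data.frame(condition = trials$condition,
                    response = trials$response,
                    rt = signif(trials$rt, 6))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar_path)) {
    lab <- attr(trials, "neglect")
    if (is.null(lab))
      stop("`trials` carries no neglect labels; generate with ",
           "`generate_dataset()`", call. = FALSE)
    write.csv(data.frame(trial_id = lab$trial_id,
                         neglect_flag = as.integer(lab$neglect)),
              sidecar_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
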