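# Posterior predictive distributions over response time and choice, and
# accumulation-trajectory summaries aligned on stimulus onset or response.

.ppc_quantiles <- c(0.1, 0.3, 0.5, 0.7, 0.9)

#' Posterior predictive summary of choice-RT distributions
#'
#' Draws `n_draws` parameter vectors uniformly from the pooled
#' post-burn-in samples (with replacement if `n_draws` exceeds the pool),
#' simulates `n_trials_per_draw` trials per condition from each, pools the
#' simulations, and summarizes per condition and response: a defective
#' density curve on a common RT grid (scaled so the two response curves of
#' a condition integrate to 1 together), the predicted choice probability,
#' and RT quantiles (0.1, 0.3, 0.5, 0.7, 0.9).
#'
#' @param fit A `sat_fit` object (or a `posterior_samples` object plus
#'   `variant`/constants defaults).
#' @param n_draws Number of posterior draws to propagate.
#' @param n_trials_per_draw Simulated trials per condition per draw.
#' @param seed Optional seed.
#' @param grid_n Number of RT grid cells for the density curves.
#' @return A list of class `predictive_summary` with elements `cells`
#'   (condition x response choice probabilities), `quantiles`, `density`
#'   (long data frame on the RT grid) and the grid itself.
#' @export
posterior_predict <- function(fit, n_draws = 100, n_trials_per_draw = 200,
                              seed = NULL, grid_n = 100L) {
  stopifnot(inherits(fit, "sat_fit"))
  draws <- posterior_draws(fit$posterior)
  if (nrow(draws) == 0L) stop("no post-burn-in samples", call. = FALSE)
  with_seed(seed, {
    take <- sample.int(nrow(draws), n_draws, replace = n_draws > nrow(draws))
    sims <- vector("list", length(take) * 3L)
    k <- 0L
    for (i in take) {
      params <- .theta_to_params(draws[i, ], fit$variant, fit$drift_sum,
                                 fit$A, fit$b_ratio)
      cfg <- generator_config(params, n_speed = n_trials_per_draw,
                              n_neutral = n_trials_per_draw,
                              n_accuracy = n_trials_per_draw)
      k <- k + 1L
      sims[[k]] <- generate_dataset(cfg)
    }
    pooled <- do.call(rbind, sims[seq_len(k)])
    attr(pooled, "neglect") <- NULL
    attr(pooled, "config") <- NULL

    grid <- seq(min(pooled$rt), max(pooled$rt), length.out = grid_n + 1L)
    bw <- diff(grid[1:2])
    mids <- grid[-1L] - bw / 2

    cells <- expand.grid(condition = .conditions, response = .responses,
                         stringsAsFactors = FALSE)
    cells$choice_prob <- NA_real_
    dens_rows <- list(); q_rows <- list()
    for (r in seq_len(nrow(cells))) {
      cond <- cells$condition[r]; resp <- cells$response[r]
      in_cond <- pooled$condition == cond
      sel <- in_cond & pooled$response == resp
      cells$choice_prob[r] <- sum(sel) / sum(in_cond)
      h <- hist(pooled$rt[sel], breaks = grid, plot = FALSE)
      dens_rows[[r]] <- data.frame(condition = cond, response = resp,
                                   t = mids,
                                   density = h$counts / (sum(in_cond) * bw))
      qs <- if (any(sel)) quantile(pooled$rt[sel], .ppc_quantiles, names = FALSE)
            else rep(NA_real_, length(.ppc_quantiles))
      q_rows[[r]] <- data.frame(condition = cond, response = resp,
                                prob = .ppc_quantiles, rt = qs)
    }
    structure(list(cells = cells,
                   quantiles = do.call(rbind, q_rows),
                   density = do.call(rbind, dens_rows),
                   grid = grid, n_draws = n_draws,
                   n_trials_per_draw = n_trials_per_draw),
              class = "predictive_summary")
  })
}

#' @export
print.predictive_summary <- function(x, ...) {
  cat("Posterior predictive summary (", x$n_draws, " draws x ",
      x$n_trials_per_draw, " trials/condition)\n", sep = "")
  print(x$cells, digits = 3)
  invisible(x)
}

#' Observed-vs-predicted discrepancy table
#'
#' Compares a trial table with a [posterior_predict()] summary: per
#' condition the observed vs predicted probability of each response, and
#' per condition-response cell the observed vs predicted RT quantiles.
#' Cells absent from the observed data are flagged (`NA` discrepancy),
#' not fatal; an empty intersection of conditions is an error.
#'
#' @param observed A trial table.
#' @param predictive A `predictive_summary`.
#' @return A data frame with columns `condition`, `response`, `measure`,
#'   `observed`, `predicted`, `diff`.
#' @export
fit_report <- function(observed, predictive) {
  .validate_trials(observed)
  stopifnot(inherits(predictive, "predictive_summary"))
  shared <- intersect(unique(observed$condition), predictive$cells$condition)
  if (length(shared) == 0L)
    stop("no conditions shared between observed data and predictive summary",
         call. = FALSE)
  rows <- list()
  for (cond in shared) {
    in_cond <- observed$condition == cond
    for (resp in .responses) {
      sel <- in_cond & observed$response == resp
      obs_p <- sum(sel) / sum(in_cond)
      pred_p <- predictive$cells$choice_prob[
        predictive$cells$condition == cond & predictive$cells$response == resp]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, response = resp, measure = "choice_prob",
        observed = obs_p, predicted = pred_p, diff = obs_p - pred_p)
      pq <- predictive$quantiles[predictive$quantiles$condition == cond &
                                 predictive$quantiles$response == resp, ]
      oq <- if (any(sel)) quantile(observed$rt[sel], .ppc_quantiles,
                                   names = FALSE)
            else rep(NA_real_, length(.ppc_quantiles))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, response = resp,
        measure = paste0("rt_q", .ppc_quantiles * 100),
        observed = oq, predicted = pq$rt, diff = oq - pq$rt)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aligned accumulation-trajectory panels
#'
#' Simulates correct-decision (target-wins) trajectories of the target
#' accumulator for each requested setting and computes a pointwise mean
#' path on a common grid. For stimulus-onset alignment, paths that have
#' already crossed are held at threshold (the mean is then nondecreasing)
#' and the grid is truncated once fewer than `min_active` paths are still
#' accumulating. For response alignment, time 0 is each path's own
#' threshold crossing, so the mean terminates exactly at the setting's
#' threshold.
#'
#' @param params A [sat_parameters()] object.
#' @param settings Character vector from `c("speed", "accuracy")`.
#' @param align `"stimulus_onset"` or `"response"`.
#' @param n_paths Trajectories per setting (`>= 1`).
#' @param dt Grid step in seconds (default 1 ms).
#' @param min_active Minimum number of paths a grid point must draw on.
#' @param seed Optional seed.
#' @return A list of class `aligned_trajectories`, one element per
#'   setting: `paths` (a `trajectory_set`), `mean` (data frame of `time`,
#'   `evidence`), `threshold`, `align`.
#' @export
trajectory_panels <- function(params, settings = c("speed", "accuracy"),
                              align = c("stimulus_onset", "response"),
                              n_paths = 50, dt = 0.001, min_active = 10L,
                              seed = NULL) {
  stopifnot(inherits(params, "sat_parameters"))
  align <- match.arg(align)
  settings <- match.arg(settings, c("speed", "accuracy"), several.ok = TRUE)
  if (n_paths < 1) stop("`n_paths` must be at least 1", call. = FALSE)
  need <- min(min_active, n_paths)
  with_seed(seed, {
    out <- list()
    for (stg in settings) {
      race <- build_race(params, stg)
      b <- race$target$b
      trj <- lba_simulate_trajectories(race, n_paths, dt = dt,
                                       winner_filter = "target")
      ct <- vapply(trj, `[[`, numeric(1), "crossing_time")
      start <- vapply(trj, `[[`, numeric(1), "start")
      drift <- vapply(trj, `[[`, numeric(1), "drift")
      if (align == "stimulus_onset") {
        t_end <- if (n_paths >= need)
          sort(ct, decreasing = TRUE)[need] else max(ct)
        grid <- seq(0, t_end, by = dt)
        ev <- vapply(grid, function(tt)
          mean(pmin(start + drift * tt, b)), numeric(1))
      } else {
        t_span <- if (n_paths >= need) sort(ct, decreasing = TRUE)[need]
                  else max(ct)
        grid <- seq(-t_span, 0, by = dt)
        grid[length(grid)] <- 0
        ev <- vapply(grid, function(tt) {
          active <- ct >= -tt
          mean(b + drift[active] * tt)
        }, numeric(1))
      }
      out[[stg]] <- list(paths = trj,
                         mean = data.frame(time = grid, evidence = ev),
                         threshold = b, align = align)
    }
    structure(out, class = "aligned_trajectories", align = align)
  })
}

#' Plot a predictive summary against observed data
#'
#' Base-graphics overlay of observed RT histograms (per condition,
#' correct/error stacked by shading) with the predictive defective
#' density curves — the standard visual posterior predictive check.
#'
#' @param x A `predictive_summary`.
#' @param observed Optional trial table to draw histograms from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.predictive_summary <- function(x, observed = NULL, ...) {
  conds <- unique(x$cells$condition)
  op <- graphics::par(mfrow = c(1, length(conds)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cond in conds) {
    d <- x$density[x$density$condition == cond, ]
    ylim <- c(0, max(d$density, na.rm = TRUE) * 1.1)
    graphics::plot(NA, xlim = range(x$grid), ylim = ylim, main = cond,
                   xlab = "RT (s)", ylab = "defective density", ...)
    if (!is.null(observed)) {
      sel <- observed$condition == cond
      if (any(sel))
        graphics::hist(observed$rt[sel], breaks = x$grid, freq = FALSE,
                       col = "grey85", border = "grey70", add = TRUE)
    }
    for (resp in .responses) {
      dd <- d[d$response == resp, ]
      graphics::lines(dd$t, dd$density,
                      lwd = 2, lty = if (resp == "target") 1 else 2)
    }
  }
  invisible(x)
}

#' Plot aligned trajectory panels
#'
#' @param x An `aligned_trajectories` object.
#' @param max_paths Thin individual paths to at most this many per setting.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aligned_trajectories <- function(x, max_paths = 20, ...) {
  align <- attr(x, "align")
  xlim <- range(unlist(lapply(x, function(p) range(p$mean$time))))
  ylim <- c(0, max(vapply(x, `[[`, numeric(1), "threshold")) * 1.05)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = if (align == "response") "time to response (s)"
                        else "time from stimulus onset (s)",
                 ylab = "evidence", ...)
  cols <- setNames(c("firebrick", "steelblue")[seq_along(x)], names(x))
  for (stg in names(x)) {
    pan <- x[[stg]]
    keep <- seq_len(min(max_paths, length(pan$paths)))
    for (i in keep) {
      pp <- pan$paths[[i]]$path
      tt <- if (align == "response") pp$time - max(pp$time) else pp$time
      graphics::lines(tt, pp$evidence, col = grDevices::adjustcolor(cols[stg], 0.25))
    }
    graphics::lines(pan$mean$time, pan$mean$evidence, col = cols[stg], lwd = 3)
    graphics::abline(h = pan$threshold, col = cols[stg], lty = 3)
  }
  graphics::legend("topleft", legend = names(x), col = cols, lwd = 3, bty = "n")
  invisible(x)
}
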