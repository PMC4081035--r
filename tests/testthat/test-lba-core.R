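test_that("accumulator and race constructors enforce their invariants", {
  expect_error(accumulator(b = -1, v = 1, s = 1), "positive")
  expect_error(accumulator(b = 1, A = 1.5, v = 1, s = 1), "below the threshold")
  expect_error(accumulator(b = 1, v = 1, s = 0), "positive")
  expect_error(accumulator(b = 1, v = NA, s = 1), "finite")
  a <- accumulator(b = 1, v = 1, s = 1)
  expect_error(race_spec(a, a, t0 = -0.1), "non-negative")
  # both drifts hopelessly negative -> race never finishes
  bad <- accumulator(b = 1, v = -8, s = 0.1)
  expect_error(race_spec(bad, bad), "finish probability")
})

test_that("fpt density concentrates at b/v in the ballistic limit", {
  acc <- accumulator(b = 1, A = 0, v = 1, s = 1e-3)
  mass <- lba_fpt_cdf(acc, 1.01) - lba_fpt_cdf(acc, 0.99)
  expect_gt(mass, 0.999)
})

test_that("fpt pdf matches a Monte-Carlo oracle (Q accuracy target, A = 0)", {
  b <- 0.24; v <- 0.66; s <- 0.10
  acc <- accumulator(b = b, v = v, s = s)
  set.seed(42)
  drift <- rnorm(1e6, v, s)
  ct <- b / drift[drift > 0]
  # normalized histogram vs analytic density, 3 standard-error bands
  breaks <- seq(0.25, 0.55, by = 0.01)
  inside <- ct[ct >= min(breaks) & ct <= max(breaks)]
  h <- hist(inside, breaks = breaks, plot = FALSE)
  n <- length(ct)
  emp_dens <- h$counts / (n * diff(breaks))
  p_bin <- diff(lba_fpt_cdf(acc, breaks)) / pnorm(v / s)
  an_dens <- p_bin / diff(breaks)
  se <- sqrt(p_bin * (1 - p_bin) / n) / diff(breaks)
  expect_lt(max(abs(emp_dens - an_dens) / se), 3)
})

test_that("fpt pdf integrates to the positive-drift probability", {
  cases <- list(c(0.24, 0, 0.66, 0.10), c(0.29, 0, -0.5, 1),
                c(0.42, 0, 1.16, 0.28), c(0.3, 0.1, 1.0, 0.5))
  for (cs in cases) {
    acc <- accumulator(b = cs[1], A = cs[2], v = cs[3], s = cs[4])
    got <- integrate(function(t) lba_fpt_pdf(acc, t), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(got, pnorm(cs[3] / cs[4]), tolerance = 1e-6)
  }
})

test_that("fpt cdf: limits, Monte-Carlo agreement and pdf consistency", {
  acc <- accumulator(b = 0.24, v = 0.66, s = 0.10)
  expect_lt(lba_fpt_cdf(acc, 1e-9), 1e-12)
  set.seed(7)
  drift <- rnorm(1e6, 0.66, 0.10)
  ct <- 0.24 / drift[drift > 0]
  emp <- mean(ct <= 0.4) * mean(drift > 0)
  expect_lt(abs(lba_fpt_cdf(acc, 0.4) - emp), 0.005)
  # finite differences of the cdf reproduce the pdf
  grid <- seq(0.28, 0.5, by = 0.01)
  h <- 1e-6
  fd <- (lba_fpt_cdf(acc, grid + h) - lba_fpt_cdf(acc, grid - h)) / (2 * h)
  expect_lt(max(abs(fd - lba_fpt_pdf(acc, grid))), 1e-4)
})

test_that("A > 0 closed form agrees with simulated crossings", {
  b <- 0.3; A <- 0.1; v <- 1.0; s <- 0.5
  acc <- accumulator(b = b, A = A, v = v, s = s)
  set.seed(11)
  start <- runif(5e5, 0, A)
  drift <- rnorm(5e5, v, s)
  ok <- drift > 0
  ct <- (b - start[ok]) / drift[ok]
  p_cross <- mean(ok)
  for (tt in c(0.1, 0.2, 0.4, 0.8))
    expect_lt(abs(lba_fpt_cdf(acc, tt) - mean(ct <= tt) * p_cross), 0.005)
  grid <- seq(0.05, 1, by = 0.01)
  h <- 1e-6
  fd <- (lba_fpt_cdf(acc, grid + h) - lba_fpt_cdf(acc, grid - h)) / (2 * h)
  expect_lt(max(abs(fd - lba_fpt_pdf(acc, grid))), 1e-4)
})

test_that("defective density: boundary, symmetry and Monte-Carlo oracle", {
  q_spd <- preset_races()$q_speed
  expect_identical(lba_defective_pdf(q_spd, "target", q_spd$t0), 0)
  expect_identical(lba_defective_pdf(q_spd, "target", 0.05), 0)

  # identical accumulators: each defective density integrates to 1/2
  a <- accumulator(b = 0.3, v = 1, s = 0.4)
  sym <- race_spec(a, a, t0 = 0.1)
  expect_equal(integrate(function(t) lba_defective_pdf(sym, "target", t),
                         0.1, Inf, rel.tol = 1e-9)$value, 0.5,
               tolerance = 1e-5)

  # winner-separated simulated cumulative mass matches the analytic curve
  sim <- lba_simulate_trials(q_spd, 1e6, seed = 3)
  for (tt in c(0.18, 0.22, 0.28, 0.4, 0.8)) {
    emp <- mean(sim$winner == "target" & sim$rt <= tt)
    an <- integrate(function(t) lba_defective_pdf(q_spd, "target", t),
                    q_spd$t0, tt, rel.tol = 1e-9)$value
    expect_lt(abs(emp - an), 0.005)
  }
})

test_that("choice probabilities: symmetry, dominance, simulation, normalization", {
  a <- accumulator(b = 0.3, v = 1, s = 0.4)
  sym <- race_spec(a, a, t0 = 0.1)
  expect_equal(lba_choice_prob(sym, "target"), 0.5, tolerance = 1e-6)

  dom <- race_spec(accumulator(b = 0.3, v = 3, s = 0.05),
                   accumulator(b = 0.3, v = 0.5, s = 0.05), t0 = 0.1)
  expect_gt(lba_choice_prob(dom, "target"), 0.999)

  s_acc <- preset_races()$s_accuracy
  sim <- lba_simulate_trials(s_acc, 1e6, seed = 5)
  expect_lt(abs(lba_choice_prob(s_acc, "target") -
                mean(sim$winner == "target")), 0.005)

  for (race in preset_races())
    expect_equal(lba_choice_prob(race, "target") +
                 lba_choice_prob(race, "distractor"), 1, tolerance = 1e-4)
})

test_that("trial simulation: degenerate limit, self-consistency, determinism", {
  det <- race_spec(accumulator(b = 0.3, v = 2, s = 1e-9),
                   accumulator(b = 0.3, v = 1, s = 1e-9), t0 = 0.1)
  sim <- lba_simulate_trials(det, 100, seed = 1)
  expect_true(all(sim$winner == "target"))
  expect_equal(sim$rt, rep(0.3 / 2 + 0.1, 100), tolerance = 1e-6)

  race <- preset_races()$q_speed
  sim <- lba_simulate_trials(race, 1e5, seed = 2)
  p <- lba_choice_prob(race, "target")
  expect_lt(abs(mean(sim$winner == "target") - p),
            4 * sqrt(p * (1 - p) / 1e5))

  expect_identical(lba_simulate_trials(race, 500, seed = 9),
                   lba_simulate_trials(race, 500, seed = 9))

  # near-zero finish probability errors out after bounded redraws
  slim <- race_spec(accumulator(b = 1, v = -5, s = 1),
                    accumulator(b = 1, v = -5, s = 1), t0 = 0)
  expect_error(lba_simulate_trials(slim, 100, seed = 1, max_attempts = 1000),
               "finish probability")
})

test_that("trajectories are ballistic, end at threshold, and match trial RTs", {
  race <- preset_races()$q_speed
  trj <- lba_simulate_trajectories(race, 40, dt = 0.001, seed = 4)
  for (tr in trj) {
    expect_equal(tr$path$evidence,
                 tr$start + tr$drift * tr$path$time, tolerance = 1e-9)
    last <- nrow(tr$path)
    expect_lt(abs(tr$path$evidence[last] - race$target$b),
              0.001 * abs(tr$drift) + 1e-9)
    expect_lte(abs(tr$path$time[last] - tr$crossing_time), 1e-12)
  }
  # mean crossing time agrees with mean decision time of matching trials
  trj_big <- lba_simulate_trajectories(race, 4000, dt = 0.01, seed = 6)
  ct <- vapply(trj_big, `[[`, numeric(1), "crossing_time")
  sim <- lba_simulate_trials(race, 4e4, seed = 7)
  dt_target <- sim$rt[sim$winner == "target"] - race$t0
  expect_lt(abs(mean(ct) - mean(dt_target)),
            4 * sd(dt_target) / sqrt(length(ct)))
  expect_identical(lba_simulate_trajectories(race, 5, seed = 8),
                   lba_simulate_trajectories(race, 5, seed = 8))
})

test_that("RT rises with threshold; choice probability rises with drift", {
  # the A = 0 race RT density has a 1/t^2 tail (near-zero drift draws
  # cross arbitrarily late), so the mean RT is infinite; location is
  # compared via the analytic median and a common-seed simulated mean
  median_rt <- function(race) {
    uniroot(function(t) lba_race_cdf(race, t) - 0.5,
            lower = race$t0 + 1e-9, upper = 100, tol = 1e-10)$root
  }
  for (b in c(0.2, 0.35)) {
    lo <- race_spec(accumulator(b = b, v = 1.2, s = 0.3),
                    accumulator(b = b, v = 0.8, s = 0.3), t0 = 0.1)
    hi <- race_spec(accumulator(b = b * 1.5, v = 1.2, s = 0.3),
                    accumulator(b = b * 1.5, v = 0.8, s = 0.3), t0 = 0.1)
    expect_gt(median_rt(hi), median_rt(lo))
    expect_gt(mean(lba_simulate_trials(hi, 2e4, seed = 33)$rt),
              mean(lba_simulate_trials(lo, 2e4, seed = 33)$rt))
  }
  for (v in c(0.8, 1.5)) {
    base <- race_spec(accumulator(b = 0.3, v = v, s = 0.3),
                      accumulator(b = 0.3, v = 0.7, s = 0.3), t0 = 0.1)
    up <- race_spec(accumulator(b = 0.3, v = v + 0.4, s = 0.3),
                    accumulator(b = 0.3, v = 0.7, s = 0.3), t0 = 0.1)
    expect_gt(lba_choice_prob(up, "target"), lba_choice_prob(base, "target"))
  }
})

test_that("simulated RT distribution matches the analytic race cdf (KS)", {
  race <- preset_races()$s_speed
  sim <- lba_simulate_trials(race, 1e5, seed = 10)
  expect_lt(ks_distance(sim$rt, function(t) lba_race_cdf(race, t)), 0.01)
})
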