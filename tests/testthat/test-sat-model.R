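test_that("construction applies the neural threshold and scaling constraints", {
  p <- sat_preset("Q")
  spd <- build_race(p, "speed")
  acc <- build_race(p, "accuracy")
  expect_identical(spd$target$b, 1.2 * 0.24)      # exactly 0.288
  expect_identical(spd$target$s, 1)               # scaling constraint
  expect_identical(spd$distractor$s, 1)
  expect_identical(spd$t0, acc$t0)                # one shared t0
  expect_identical(spd$target$b, spd$distractor$b)
  expect_identical(acc$target$s, acc$distractor$s)
  expect_error(sat_parameters(t0 = 0.1, b_acc = 0.2, v_t_acc = 1,
                              v_d_acc = 1, v_t_spd = 1, v_d_spd = 1,
                              s_acc = 0.1, p = 1.2), "\\[0, 1\\]")
})

test_that("free parameter names: 7 core plus the flagged mixture proportion", {
  core <- sat_free_parameter_names(core_only = TRUE)
  expect_length(core, 7L)
  full <- sat_free_parameter_names()
  expect_true("p" %in% full)
  expect_false(attr(full, "core")[full == "p"])
  expect_identical(sum(attr(full, "core")), 7L)
  expect_false(anyDuplicated(full) > 0)
})

test_that("mixture endpoints and the speed/neutral yoking hold exactly", {
  base <- preset_truth("Q")
  mk <- function(p) sat_parameters(t0 = base$t0, b_acc = base$b_acc,
                                   v_t_acc = base$v_t_acc, v_d_acc = base$v_d_acc,
                                   v_t_spd = base$v_t_spd, v_d_spd = base$v_d_spd,
                                   s_acc = base$s_acc, p = p)
  rts <- seq(0.12, 0.9, by = 0.06)
  for (resp in c("target", "distractor")) {
    p0 <- mk(0)
    expect_equal(trial_density(p0, "accuracy", resp, rts),
                 lba_defective_pdf(build_race(p0, "accuracy"), resp, rts))
    p1 <- mk(1)
    expect_equal(trial_density(p1, "accuracy", resp, rts),
                 trial_density(p1, "speed", resp, rts))
    pm <- mk(0.3)
    expect_identical(trial_density(pm, "neutral", resp, rts),
                     trial_density(pm, "speed", resp, rts))
  }
  expect_error(trial_density(mk(0.1), "fast", "target", 0.3),
               "unknown condition")
})

test_that("dataset log-likelihood: additivity, oracle match, engine agreement", {
  p <- sat_preset("Q")
  tab <- tiny_trials()
  ll <- dataset_loglik(p, tab, engine = "r")
  expect_equal(dataset_loglik(p, rbind(tab, tab), engine = "r"), 2 * ll,
               tolerance = 1e-12)
  # independent scalar re-implementation as oracle
  expect_equal(ll, oracle_loglik(preset_truth("Q"), tab), tolerance = 1e-10)
  expect_equal(dataset_loglik(p, tab, engine = "cpp"), ll, tolerance = 1e-10)
  expect_error(dataset_loglik(p, tab[0, ]), "non-empty")

  # engines agree across random parameter vectors
  set.seed(21)
  for (i in 1:20) {
    pr <- sat_parameters(t0 = runif(1, 0, 0.18), b_acc = runif(1, 0.1, 0.6),
                         v_t_acc = runif(1, -1, 3), v_d_acc = runif(1, -1, 3),
                         v_t_spd = runif(1, 0, 4), v_d_spd = runif(1, 0, 4),
                         s_acc = runif(1, 0.05, 1), p = runif(1))
    expect_equal(dataset_loglik(pr, tab, engine = "cpp"),
                 dataset_loglik(pr, tab, engine = "r"), tolerance = 1e-8)
  }
})

test_that("generating parameters beat a distorted model on synthetic data", {
  p <- sat_preset("Q")
  tab <- generate_dataset(generator_config(p, 2500, 0, 2500, seed = 31))
  distorted <- sat_parameters(t0 = p$t0, b_acc = 2 * p$b_acc,
                              v_t_acc = p$v_t_acc, v_d_acc = p$v_d_acc,
                              v_t_spd = p$v_t_spd, v_d_spd = p$v_d_spd,
                              s_acc = p$s_acc, p = p$p)
  expect_gt(dataset_loglik(p, tab), dataset_loglik(distorted, tab))
})

test_that("likelihood is invariant to a common evidence-scale factor", {
  # rescaling b, A, v and s together leaves every density unchanged --
  # the reason one parameter (the speed-setting s) must be fixed
  scale <- 3.7
  r1 <- race_spec(accumulator(b = 0.3, A = 0.05, v = 1.1, s = 0.4),
                  accumulator(b = 0.3, A = 0.05, v = 0.6, s = 0.4), t0 = 0.1)
  r2 <- race_spec(accumulator(b = 0.3 * scale, A = 0.05 * scale,
                              v = 1.1 * scale, s = 0.4 * scale),
                  accumulator(b = 0.3 * scale, A = 0.05 * scale,
                              v = 0.6 * scale, s = 0.4 * scale), t0 = 0.1)
  ts <- seq(0.12, 1.2, by = 0.04)
  expect_equal(lba_defective_pdf(r1, "target", ts),
               lba_defective_pdf(r2, "target", ts), tolerance = 1e-12)
  expect_equal(lba_defective_pdf(r1, "distractor", ts),
               lba_defective_pdf(r2, "distractor", ts), tolerance = 1e-12)
})

test_that("log-likelihood is smooth in every free parameter", {
  p <- sat_preset("Q")
  tab <- generate_dataset(generator_config(p, 150, 30, 150, seed = 41))
  theta0 <- c(t0 = p$t0, b_acc = p$b_acc, v_t_acc = p$v_t_acc,
              v_d_acc = p$v_d_acc, v_t_spd = p$v_t_spd, v_d_spd = p$v_d_spd,
              s_acc = p$s_acc, p = p$p)
  ll_at <- function(th) dataset_loglik(do.call(sat_parameters, as.list(th)),
                                       tab)
  for (nm in names(theta0)) {
    for (h in c(1e-3, 1e-4)) {
      up <- theta0; up[nm] <- up[nm] + h
      dn <- theta0; dn[nm] <- dn[nm] - h
      d1 <- (ll_at(up) - ll_at(dn)) / (2 * h)
      expect_true(is.finite(d1))
    }
    # derivative estimates at the two step sizes agree (no jumps)
    h1 <- 1e-3; h2 <- 5e-4
    g <- function(h) {
      up <- theta0; up[nm] <- up[nm] + h
      dn <- theta0; dn[nm] <- dn[nm] - h
      (ll_at(up) - ll_at(dn)) / (2 * h)
    }
    expect_lt(abs(g(h1) - g(h2)), 0.05 * (abs(g(h2)) + 1))
  }
})

test_that("over-constrained variant removes drift freedom and round-trips", {
  p <- sat_preset("Q")
  v <- over_constrained_variant(p, drift_sum = 1)
  expect_equal(v$v_t_acc + v$v_d_acc, 1)
  expect_equal(v$v_t_spd + v$v_d_spd, 1)
  expect_identical(attr(v, "variant"), "over_constrained")
  expect_lt(length(sat_priors("over_constrained")),
            length(sat_priors("main")))
  expect_identical(over_constrained_variant(p, apply = FALSE), p)
})

test_that("trial tables round-trip through disk with their sidecar", {
  tab <- generate_dataset(generator_config(sat_preset("Q"), 30, 10, 30,
                                           seed = 51))
  path <- tempfile(fileext = ".csv")
  side <- tempfile(fileext = ".csv")
  write_trial_table(tab, path, sidecar_path = side)
  back <- read_trial_table(path)
  expect_identical(back$condition, tab$condition)
  expect_identical(back$response, tab$response)
  expect_equal(back$rt, tab$rt, tolerance = 1e-5)
  lab <- read.csv(side)
  expect_identical(nrow(lab), 30L)
  expect_equal(mean(lab$neglect_flag), neglect_fraction(tab))
  expect_error(read_trial_table(tempfile()), "not found")
  bad <- tab; bad$condition[1] <- "warp"
  expect_error(write_trial_table(bad, path), "condition")
})
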