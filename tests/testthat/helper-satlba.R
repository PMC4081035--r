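# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written from first principles (scalar,
# mean/sd-parameterized normals) and never call the package's vectorized
# or compiled paths.

preset_truth <- function(monkey) {
  if (monkey == "Q")
    list(t0 = 0.10, b_acc = 0.24, v_t_acc = 0.66, v_d_acc = 0.40,
         v_t_spd = 2.30, v_d_spd = 1.41, s_acc = 0.10, p = 0.08)
  else
    list(t0 = 0.09, b_acc = 0.42, v_t_acc = 1.16, v_d_acc = 0.81,
         v_t_spd = 2.78, v_d_spd = 2.11, s_acc = 0.28, p = 0.12)
}

# Scalar density of one (setting, response) race at observed rt; A = 0.
# Crossing time is b / drift with drift ~ N(v, s); only positive drifts
# cross, and the race density is renormalized by its finish probability.
oracle_setting_density <- function(b, v_t, v_d, s, t0, response, rt) {
  tau <- rt - t0
  if (tau <= 0) return(0)
  v_w <- if (response == "target") v_t else v_d
  v_l <- if (response == "target") v_d else v_t
  f_w <- b / tau^2 * dnorm(b / tau, mean = v_w, sd = s)
  surv_l <- pnorm(b / tau, mean = v_l, sd = s) # loser has not yet crossed
  Z <- 1 - pnorm(0, v_t, s) * pnorm(0, v_d, s)
  f_w * surv_l / Z
}

# Scalar mixture density of one trial under the constrained model.
oracle_trial_density <- function(tr, condition, response, rt) {
  spd <- oracle_setting_density(1.2 * tr$b_acc, tr$v_t_spd, tr$v_d_spd, 1,
                                tr$t0, response, rt)
  if (condition != "accuracy") return(spd)
  acc <- oracle_setting_density(tr$b_acc, tr$v_t_acc, tr$v_d_acc, tr$s_acc,
                                tr$t0, response, rt)
  (1 - tr$p) * acc + tr$p * spd
}

oracle_loglik <- function(tr, trials, floor = 1e-29) {
  ll <- 0
  for (i in seq_len(nrow(trials)))
    ll <- ll + log(max(oracle_trial_density(tr, trials$condition[i],
                                            trials$response[i],
                                            trials$rt[i]), floor))
  ll
}

# Small deterministic trial fixture spanning all conditions and responses.
tiny_trials <- function() {
  data.frame(
    condition = c("speed", "speed", "neutral", "neutral", "accuracy",
                  "accuracy", "accuracy", "speed", "accuracy", "neutral"),
    response = c("target", "distractor", "target", "target", "target",
                 "distractor", "target", "target", "target", "distractor"),
    rt = c(0.22, 0.25, 0.21, 0.30, 0.45, 0.52, 0.24, 0.19, 0.61, 0.23),
    stringsAsFactors = FALSE)
}

# The four parameter-setting races implied by the two published presets.
preset_races <- function() {
  list(q_accuracy = build_race(sat_preset("Q"), "accuracy"),
       q_speed = build_race(sat_preset("Q"), "speed"),
       s_accuracy = build_race(sat_preset("S"), "accuracy"),
       s_speed = build_race(sat_preset("S"), "speed"))
}

# Kolmogorov distance between a sample and an analytic cdf.
ks_distance <- function(x, cdf_fun) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf_fun(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}
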