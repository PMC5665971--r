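test_that("tap series container enforces its structural invariants", {
  ev_ok <- data.frame(event = c("lift", "drop", "lift", "drop"),
                      time = c(0.4, 0.5, 0.9, 1.0))
  s <- tap_series(ev_ok, "s1", "b1", "near", "rhythmic", duration = 60)
  expect_s3_class(s, "tap_series")
  expect_equal(drop_times(s), c(0.5, 1.0))
  bad_order <- ev_ok[c(2, 1, 3, 4), ]
  expect_error(tap_series(bad_order, "s1", "b1", "near", "rhythmic", 60),
               "increasing")
  bad_alt <- data.frame(event = c("drop", "lift"), time = c(0.1, 0.2))
  expect_error(tap_series(bad_alt, "s1", "b1", "near", "rhythmic", 60),
               "alternate")
  late <- data.frame(event = c("lift", "drop"), time = c(59.9, 61))
  expect_error(tap_series(late, "s1", "b1", "near", "rhythmic", 60),
               "within")
})

test_that("uncoupled tapper paces at mu and is deterministic per seed", {
  env <- make_envelope(envelope_spec("constant", duration = 60,
                                     sample_rate = 100))
  tp <- tapper(0.7, sigma = 0.05)
  blk <- simulate_rhythmic_block(tp, env, 60, seed = 4)
  iv <- diff(drop_times(blk))
  expect_lt(abs(mean(iv) - 0.7), 3 * 0.05 / sqrt(length(iv)))
  blk2 <- simulate_rhythmic_block(tp, env, 60, seed = 4)
  expect_identical(blk$events, blk2$events)
  # structural invariants hold across seeds
  for (s in 1:20) {
    b <- simulate_rhythmic_block(tapper(0.5, sigma = 0.08,
                                        sigma_tempo = 0.01,
                                        lapse_prob = 0.1), env, 60, seed = s)
    ev <- b$events
    expect_true(all(diff(ev$time) > 0))
    expect_identical(ev$event, rep(c("lift", "drop"),
                                   length.out = nrow(ev)))
  }
})

test_that("noiseless commensurate tapping locks every drop to one phase", {
  env <- sine_env(2, duration = 60)
  tp <- tapper(0.5, sigma = 0)
  blk <- simulate_rhythmic_block(tp, env, 60, seed = 1)
  ph <- phase_at(env, drop_times(blk))
  expect_lt(diff(range(ph)), 1e-6)
})

test_that("coupled tapping concentrates drop phases around psi", {
  mu <- 0.7
  env <- sine_env(1 / mu, duration = 60)
  rej <- 0
  for (s in 1:40) {
    tp <- tapper(mu, sigma = 0.07, kappa = 0.8, psi = 120)
    blk <- suppressWarnings(simulate_rhythmic_block(tp, env, 60, seed = s))
    ph <- phase_at(env, drop_times(blk))
    # mean direction near psi (lock offset is small at zero detuning)
    expect_lt(abs(((circ_mean(ph) - 120 + 180) %% 360) - 180), 35)
    if (rao_test(ph, n_null = 10000, seed = s)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 40, 0.95)
})

test_that("rhythmic entrainment strength is monotone in kappa", {
  mu <- 0.694
  env <- sine_env(1 / mu, duration = 60)
  mean_U <- vapply(c(0, 0.2, 0.5, 0.8), function(k) {
    mean(vapply(1:25, function(s) {
      tp <- tapper(mu, sigma = 0.07, kappa = k, psi = 90)
      blk <- suppressWarnings(simulate_rhythmic_block(tp, env, 60,
                                                      seed = 100 + s))
      rao_spacing_U(phase_at(env, drop_times(blk)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_U) > 0))
})

test_that("moderate coupling at 1.5x detuning looks like no coupling", {
  mu <- 0.694
  env <- sine_env(1.5 / mu, duration = 60)
  us <- function(k) vapply(1:30, function(s) {
    tp <- tapper(mu, sigma = 0.07, kappa = k, psi = 90)
    blk <- suppressWarnings(simulate_rhythmic_block(tp, env, 60,
                                                    seed = 200 + s))
    rao_spacing_U(phase_at(env, drop_times(blk)))
  }, numeric(1))
  expect_gt(t.test(us(0.2), us(0))$p.value, 0.05)
})

test_that("single-tap trials have the right structure and phase behavior", {
  env <- sine_env(1.44, duration = 200, sample_rate = 200)
  tp0 <- tapper(0.7, kappa = 0)
  s0 <- simulate_single_tap_trials(tp0, env, n_trials = 30, seed = 1)
  expect_equal(sum(s0$events$event == "drop"), 30)
  expect_equal(nrow(s0$events), 60)
  expect_true(all(diff(s0$events$time) > 0))
  expect_identical(s0$events, simulate_single_tap_trials(
    tp0, env, n_trials = 30, seed = 1)$events)
  # kappa = 0: phases uniform (chi-square over 8 bins, pooled trials)
  ph <- unlist(lapply(1:25, function(s) {
    st <- simulate_single_tap_trials(tp0, env, n_trials = 30, seed = s)
    phase_at(env, drop_times(st))
  }))
  counts <- table(cut(ph, seq(0, 360, by = 45)))
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # large kappa: circular mean within 10 degrees of psi
  tpk <- tapper(0.7, kappa = 8, psi = 200)
  env_long <- sine_env(1.44, duration = 2600, sample_rate = 100)
  stk <- simulate_single_tap_trials(tpk, env_long, n_trials = 500, seed = 2)
  phk <- phase_at(env_long, drop_times(stk))
  expect_lt(abs(((circ_mean(phk) - 200 + 180) %% 360) - 180), 10)
})

test_that("preferred rate estimation inverts the mean interval", {
  drops <- seq(0.5, 30, by = 0.5)
  s <- tap_series(data.frame(event = rep(c("lift", "drop"), length(drops)),
                             time = as.vector(rbind(drops - 0.1, drops))),
                  "s1", "b1", "estimation", "rhythmic", 31)
  expect_equal(estimate_preferred_rate(s), 2.0)
  two <- tap_series(data.frame(event = c("lift", "drop", "lift", "drop",
                                         "lift", "drop"),
                               time = c(0.1, 0.2, 0.7, 0.8, 1.5, 1.6)),
                    "s1", "b1", "estimation", "rhythmic", 2)
  expect_equal(estimate_preferred_rate(two), 1 / 0.7)
  one <- tap_series(data.frame(event = c("lift", "drop"), time = c(0.1, 0.2)),
                    "s1", "b1", "estimation", "rhythmic", 2)
  expect_error(estimate_preferred_rate(one), "at least 2")
  # recovery from the generator near the group-typical rate
  env <- make_envelope(envelope_spec("constant", duration = 30,
                                     sample_rate = 100))
  rates <- vapply(1:100, function(s) {
    blk <- simulate_rhythmic_block(tapper(0.694, sigma = 0.05), env, 30,
                                   seed = s)
    estimate_preferred_rate(blk)
  }, numeric(1))
  expect_lt(max(abs(rates - 1.44)), 0.1 + 0.01)
  expect_lt(abs(mean(rates) - 1.44), 0.02)
})

test_that("condition rule maps rate to the right envelope spec", {
  near <- condition_frequency(1.44, "near")
  expect_equal(near$kind, "sine")
  expect_equal(near$frequency, 1.44)
  far <- condition_frequency(2.0, "far")
  expect_equal(far$frequency, 3.0)
  base <- condition_frequency(1.2, "baseline")
  expect_equal(base$kind, "poisson_pulse")
  expect_equal(base$lambda, 1)
  est <- condition_frequency(1.2, "estimation")
  expect_equal(est$kind, "constant")
  expect_error(condition_frequency(-1, "near"), "rate")
  expect_error(condition_frequency(1, "nearby"))
})
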