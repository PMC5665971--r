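make_utable <- function(subjects, conditions, blocks, U) {
  df <- expand.grid(block_id = blocks, condition = conditions,
                    subject_id = subjects, stringsAsFactors = FALSE)
  df <- df[c("subject_id", "condition", "block_id")]
  df$U <- U
  df$n_taps <- 50L
  df$excluded <- FALSE
  df$reason <- ""
  class(df) <- c("u_table", "data.frame")
  df
}

test_that("per-block phases and U handle extremes and pairing errors", {
  env <- sine_env(2, duration = 30)
  # drops at the same phase every cycle: maximal U
  drops <- seq(0.5, 29.5, by = 0.5)
  s <- tap_series(data.frame(event = rep(c("lift", "drop"), length(drops)),
                             time = as.vector(rbind(drops - 0.1, drops))),
                  "s1", "b1", "near", "rhythmic", 30)
  ut <- phases_and_U_per_block(list(s), list(b1 = env))
  n <- length(drops)
  expect_equal(ut$U, 360 * (n - 1) / n)
  expect_equal(ut$n_taps, n)
  # drops rotating evenly through phase: U = 0
  env1 <- sine_env(1, duration = 40)
  d2 <- cumsum(rep(1 + 1 / 30, 30))  # 12 deg advance per drop, 30 drops
  s2 <- tap_series(data.frame(event = rep(c("lift", "drop"), length(d2)),
                              time = as.vector(rbind(d2 - 0.1, d2))),
                   "s2", "b2", "near", "rhythmic", 40)
  ut2 <- phases_and_U_per_block(list(s2), list(b2 = env1))
  expect_equal(ut2$U, 0, tolerance = 1e-9)
  expect_error(phases_and_U_per_block(list(s), list(zz = env)),
               "no envelope")
  # single-tap blocks pool per subject x condition
  st <- simulate_single_tap_trials(tapper(0.7), sine_env(1.44, 200),
                                   n_trials = 10, seed = 1,
                                   subject_id = "s9", block_id = "p1")
  st2 <- simulate_single_tap_trials(tapper(0.7), sine_env(1.44, 200),
                                    n_trials = 10, seed = 2,
                                    subject_id = "s9", block_id = "p2")
  utp <- phases_and_U_per_block(list(st, st2),
                                list(p1 = sine_env(1.44, 200),
                                     p2 = sine_env(1.44, 200)))
  expect_equal(nrow(utp), 1)
  expect_equal(utp$n_taps, 20)
  expect_equal(utp$block_id, "pooled")
})

test_that("IQR outlier rule excludes by the 2.5 x IQR criterion", {
  ut <- make_utable("s1", "near", paste0("b", 1:5),
                    c(90, 100, 110, 120, 500))
  out <- exclude_outliers(ut, "block")
  # median 110, IQR 20, threshold 50: only 500 is out
  expect_identical(out$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  same <- make_utable("s1", "near", paste0("b", 1:4), rep(100, 4))
  expect_warning(out2 <- exclude_outliers(same, "block"), "IQR is 0")
  expect_false(any(out2$excluded))
  close3 <- make_utable("s1", "near", paste0("b", 1:3), c(100, 101, 102))
  expect_false(any(exclude_outliers(close3, "block")$excluded))
  # subject level: one subject far off the cohort excluded entirely
  U9 <- c(as.vector(rbind(95 + 2 * (1:8), 105 + 2 * (1:8))), 300, 310)
  ut3 <- make_utable(paste0("s", 1:9), "near", paste0("b", 1:2), NA)
  ut3 <- ut3[order(ut3$subject_id), ]
  ut3$U <- U9
  out3 <- exclude_outliers(ut3, "subject")
  expect_true(all(out3$excluded[out3$subject_id == "s9"]))
  expect_false(any(out3$excluded[out3$subject_id != "s9"]))
})

test_that("averaging and pooled midranks follow the standard conventions", {
  ut <- make_utable(paste0("s", 1:2), c("near", "baseline"), "b1",
                    c(10, 20, 20, 30))
  rk <- average_and_rank(ut)
  expect_equal(sort(rk$rank), c(1, 2.5, 2.5, 4))
  expect_equal(sum(rk$rank), 4 * 5 / 2)
  single <- make_utable("s1", "near", "b1", 42)
  expect_equal(average_and_rank(single)$rank, 1)
  # excluded blocks do not contribute to the mean
  ut2 <- make_utable("s1", "near", paste0("b", 1:3), c(100, 120, 999))
  ut2$excluded[3] <- TRUE
  expect_equal(average_and_rank(ut2)$mean_U, 110)
  # rank pipeline is invariant under monotone transforms of U
  set.seed(1)
  ut3 <- make_utable(paste0("s", 1:5), c("near", "baseline"), "b1",
                     runif(10, 50, 250))
  ut4 <- ut3
  ut4$U <- exp(ut3$U / 60)
  expect_equal(average_and_rank(ut3)$rank, average_and_rank(ut4)$rank)
})

test_that("mixed model detects a shifted condition and not a null one", {
  set.seed(2)
  subjects <- paste0("s", 1:10)
  base <- data.frame(subject_id = rep(subjects, each = 2),
                     condition = rep(c("near", "baseline"), 10))
  # identical ranks across conditions within every subject: p ~ 1
  null_df <- base
  null_df$rank <- rep(seq(2, 20, by = 2), each = 2)
  m0 <- fit_condition_model(null_df)
  expect_lt(m0$lrt$statistic, 1e-6)
  expect_gt(m0$lrt$p, 0.99)
  # constant separation in every subject, no noise: strongly significant
  sep <- base
  sep$rank <- ifelse(sep$condition == "near", 11:20, 1:10)
  m1 <- fit_condition_model(sep)
  expect_lt(m1$lrt$p, 1e-4)
  expect_true("condition" %in% rownames(m1$f_test))
  expect_error(fit_condition_model(null_df[null_df$condition == "near", ]),
               "conditions")
})

test_that("paired permutation contrast matches exhaustive sign flips", {
  df <- data.frame(subject_id = rep(paste0("s", 1:3), each = 2),
                   condition = rep(c("a", "b"), 3),
                   mean_U = c(110, 100, 112, 100, 111, 100))
  ct <- permutation_contrast(df, "a", "b", n_iter = 5000, seed = 3)
  expect_equal(ct$observed_diff, 11)
  # exhaustive two-sided: only +/-(10+12+11) reaches |33|, p = 2/8
  expect_lt(abs(ct$p - 2 / 8), 0.02)
  # symmetry under swapping labels
  ct2 <- permutation_contrast(df, "b", "a", n_iter = 5000, seed = 3)
  expect_equal(ct2$observed_diff, -11)
  expect_equal(ct2$p, ct$p)
  # all differences zero: p = 1
  df0 <- df
  df0$mean_U <- rep(c(100, 100), 3)
  expect_equal(permutation_contrast(df0, "a", "b", seed = 1)$p, 1)
  # reproducible for a fixed seed
  expect_identical(permutation_contrast(df, "a", "b", seed = 9)$p,
                   permutation_contrast(df, "a", "b", seed = 9)$p)
  # subjects missing a condition are dropped with a warning
  df_miss <- rbind(df, data.frame(subject_id = "s4", condition = "a",
                                  mean_U = 150))
  expect_warning(permutation_contrast(df_miss, "a", "b", seed = 1),
                 "dropped")
})

test_that("mini-block partition sizes and ordering follow the remainder
           rule", {
  expect_equal(entrainr:::miniblock_sizes(100, 10), rep(10, 10))
  expect_equal(entrainr:::miniblock_sizes(23, 10),
               c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  env <- sine_env(2, duration = 60)
  blk <- simulate_rhythmic_block(tapper(0.5, sigma = 0.05), env, 60,
                                 seed = 8)
  mb <- miniblock_analysis(list(blk), list(sim = env), n_miniblocks = 10)
  expect_equal(nrow(mb), 10)
  expect_equal(mb$miniblock, 1:10)
  expect_equal(sum(mb$n_taps), length(drop_times(blk)))
  # too few taps: block skipped with a warning
  short <- simulate_rhythmic_block(tapper(0.5, sigma = 0.01), env, 8,
                                   seed = 1)
  expect_warning(res <- miniblock_analysis(list(short), list(sim = env),
                                           n_miniblocks = 10), "skipped")
})
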