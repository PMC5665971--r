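test_that("tap-event files round-trip exactly", {
  coh <- tiny_cohort(seed = 11, n_subjects = 3, blocks_per_condition = 1)
  path <- tempfile(fileext = ".tsv")
  write_tap_events(coh$taps, path)
  back <- read_tap_events(path)
  expect_setequal(names(back), names(coh$taps))
  for (bid in names(coh$taps)) {
    expect_equal(back[[bid]]$events$time, coh$taps[[bid]]$events$time,
                 tolerance = 1e-6)
    expect_identical(back[[bid]]$events$event, coh$taps[[bid]]$events$event)
    expect_identical(back[[bid]]$condition, coh$taps[[bid]]$condition)
    expect_identical(back[[bid]]$task, coh$taps[[bid]]$task)
  }
  # write(read(f)) is a fixed point
  path2 <- tempfile(fileext = ".tsv")
  write_tap_events(back, path2)
  expect_identical(readLines(path)[order(readLines(path))],
                   readLines(path2)[order(readLines(path2))])
})

test_that("malformed tap files are rejected with row numbers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tblock_id\tcondition\ttask\tevent\ttime_s",
               "s1\tb1\tnear\trhythmic\tdrop\t0.5",
               "s1\tb1\tnear\trhythmic\tlift\t0.9"), path)
  expect_error(read_tap_events(path), "alternation.*row")
  writeLines(c("subject_id\tblock_id\tcondition\ttask\tevent\ttime_s",
               "s1\tb1\tnear\trhythmic\tlift\t0.5",
               "s1\tb1\tnear\trhythmic\tdrop\t0.4"), path)
  expect_error(read_tap_events(path), "non-increasing.*row")
  writeLines("subject_id\tblock_id\tcondition\ttask", path)
  expect_error(read_tap_events(path), "missing column")
  writeLines("subject_id\tblock_id\tcondition\ttask\tevent\ttime_s", path)
  expect_length(read_tap_events(path), 0)
})

test_that("paired blocks implement the estimation -> condition protocol", {
  cfg <- session_config(seed = 5, mu_drift_sd = 0, sigma_tempo = 0,
                        lapse_prob = 0)
  tp <- tapper(0.5, sigma = 0)
  near <- run_paired_blocks(cfg, tp, "near", "sX", 1)
  expect_equal(near$estimation$condition, "estimation")
  expect_equal(near$estimation$duration, 30)
  expect_equal(near$main$duration, 60)
  expect_equal(near$envelope$spec$frequency, 2.0, tolerance = 1e-9)
  far <- run_paired_blocks(cfg, tp, "far", "sX", 1)
  expect_equal(far$envelope$spec$frequency, 3.0, tolerance = 1e-9)
  base <- run_paired_blocks(cfg, tp, "baseline", "sX", 1)
  expect_equal(base$envelope$spec$kind, "poisson_pulse")
  expect_equal(base$envelope$spec$lambda, 1)
})

test_that("a full cohort run is reproducible from the master seed", {
  c1 <- tiny_cohort(seed = 21, n_subjects = 2, blocks_per_condition = 1)
  c2 <- tiny_cohort(seed = 21, n_subjects = 2, blocks_per_condition = 1)
  for (bid in names(c1$taps))
    expect_identical(c1$taps[[bid]]$events, c2$taps[[bid]]$events)
  f1 <- suppressWarnings(entrain_fit(c1$taps, c1$envelopes, n_iter = 500,
                                     seed = 2))
  f2 <- suppressWarnings(entrain_fit(c2$taps, c2$envelopes, n_iter = 500,
                                     seed = 2))
  expect_identical(f1$contrasts$near$p, f2$contrasts$near$p)
  expect_identical(f1$u_table$U, f2$u_table$U)
  c3 <- tiny_cohort(seed = 22, n_subjects = 2, blocks_per_condition = 1)
  expect_false(identical(c1$taps[[1]]$events, c3$taps[[1]]$events))
})

test_that("entrain_fit assembles the pipeline and honors the awareness
           filter", {
  coh <- tiny_cohort(seed = 31, kappa = c(near = 0.8), n_subjects = 6,
                     blocks_per_condition = 2)
  fit <- suppressWarnings(entrain_fit(coh$taps, coh$envelopes,
                                      n_iter = 500, seed = 1))
  expect_s3_class(fit, "entrain_fit")
  expect_true(all(c("near", "far", "baseline") %in%
                    fit$ranked$condition))
  expect_named(fit$contrasts, c("far", "near"), ignore.order = TRUE)
  expect_output(print(fit), "Entrainment analysis fit")
  sm <- summary(fit)
  expect_output(print(sm), "Permutation contrasts")
  expect_type(coef(fit), "double")
  # awareness filter removes flagged subjects before analysis
  taps2 <- coh$taps
  aware_subj <- "s01"
  for (bid in names(taps2))
    if (taps2[[bid]]$subject_id == aware_subj) taps2[[bid]]$aware <- TRUE
  fit2 <- suppressWarnings(entrain_fit(taps2, coh$envelopes, n_iter = 500,
                                       seed = 1,
                                       aware_filter = "unaware_only"))
  expect_false(aware_subj %in% fit2$ranked$subject_id)
  expect_equal(fit2$log$subjects_in, 5)
})
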