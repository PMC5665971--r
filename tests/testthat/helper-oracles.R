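# Independent brute-force implementation of the spacing statistic, written
# directly from its definition (sort, successive arcs, wrap-around arc,
# half the total absolute deviation from 360/n). Used as the oracle for the
# fast implementation.
brute_force_U <- function(angles) {
  a <- sort(angles)
  n <- length(a)
  spacings <- numeric(n)
  for (i in seq_len(n - 1)) spacings[i] <- a[i + 1] - a[i]
  spacings[n] <- 360 - a[n] + a[1]
  total <- 0
  for (i in seq_len(n)) total <- total + abs(spacings[i] - 360 / n)
  total / 2
}

# small standard cohort used across tests (kept small for speed)
tiny_cohort <- function(seed, kappa = 0, n_subjects = 8,
                        blocks_per_condition = 2) {
  cfg <- session_config(n_subjects = n_subjects,
                        blocks_per_condition = blocks_per_condition,
                        n_iter = 500, seed = seed, kappa = kappa)
  simulate_cohort(cfg)
}

# sine envelope shorthand for block-level tests
sine_env <- function(frequency, duration = 60, sample_rate = 500)
  make_envelope(envelope_spec("sine", frequency = frequency,
                              duration = duration,
                              sample_rate = sample_rate))
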