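#' Session configuration
#'
#' Collects every knob of a simulated experiment session: block durations
#' (30 s estimation, 60 s main), the condition list, stimulus parameters
#' (22050 Hz audio; envelope phase tracks for analysis are sampled at
#' `phase_rate`, which only needs to resolve tap-time phase lookup),
#' analysis parameters and the master seed. Every stochastic component
#' derives its own sub-seed deterministically from the master seed and its
#' identifiers, so a full simulate-analyze-surrogate run is bit-reproducible
#' and each component is independently re-runnable.
#'
#' @param n_subjects cohort size (default 27, the rhythmic-task cohort).
#' @param conditions conditions each subject performs.
#' @param blocks_per_condition paired blocks per condition (default 3).
#' @param estimation_duration,main_duration block durations, seconds.
#' @param task `"rhythmic"` or `"single_tap"`.
#' @param n_trials single-tap trials per block.
#' @param sample_rate audio sampling rate, Hz.
#' @param phase_rate envelope phase-track sampling rate used for
#'   simulation/analysis, Hz.
#' @param p_min,p_max spike probability bounds.
#' @param beta spectral exponent of the noise.
#' @param lambda,pulse_width baseline envelope parameters (seconds).
#' @param mu_mean,mu_sd cohort distribution of preferred intervals, seconds
#'   (defaults emulate a 1.44 Hz group mean).
#' @param sigma white interval noise SD, seconds.
#' @param sigma_tempo within-block tempo-drift step per tap, seconds.
#' @param lapse_prob per-tap probability of an attentional pause; see
#'   [tapper()].
#' @param mu_drift_sd block-to-block drift of the preferred interval,
#'   seconds: each block (estimation and main independently) is performed
#'   at `mu + N(0, mu_drift_sd)`, so the rate estimated in the 30 s
#'   estimation block differs slightly from the rate actually produced in
#'   the main block, as it does between two real blocks.
#' @param kappa coupling strength: a single value applied in every
#'   condition, or a named vector per condition (e.g.
#'   `c(near = 0.8, far = 0, baseline = 0)` for coupling that is only
#'   effective when the modulation frequency matches the tapper).
#' @param psi_spread subjects' preferred phases are drawn uniformly, so
#'   locking angles differ across subjects; kept as a marker field.
#' @param n_iter permutation iterations; `n_sim` surrogate simulations;
#'   `n_miniblocks` mini-block count; `alpha` nominal level.
#' @param n_sim,n_miniblocks,alpha see above.
#' @param seed master seed.
#' @return an object of class `"session_config"`.
#' @export
session_config <- function(n_subjects = 27,
                           conditions = c("near", "far", "baseline"),
                           blocks_per_condition = 3,
                           estimation_duration = 30, main_duration = 60,
                           task = "rhythmic", n_trials = 15,
                           sample_rate = 22050, phase_rate = 500,
                           p_min = 0.05, p_max = 0.1, beta = 1.5,
                           lambda = 1, pulse_width = 0.35,
                           mu_mean = 0.694, mu_sd = 0.06, sigma = 0.07,
                           sigma_tempo = 0.008, mu_drift_sd = 0.05,
                           lapse_prob = 0.14,
                           kappa = 0, psi_spread = "uniform",
                           n_iter = 5000, n_sim = 1000, n_miniblocks = 10,
                           alpha = 0.05, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "session_config")
}

#' Run one estimation/main block pair
#'
#' The session protocol: the subject first taps for 30 s under steady
#' unmodulated noise (the estimation block); the preferred rate estimated
#' from that block sets the main block's modulation frequency through the
#' condition rule ([condition_frequency()]); the subject then performs the
#' 60 s main block against that envelope.
#'
#' @param config a [session_config()].
#' @param tapper a [tapper()].
#' @param condition `"near"`, `"far"` or `"baseline"`.
#' @param subject_id,block_index identifiers; with `config$seed` they
#'   determine every sub-seed.
#' @return list with `estimation` and `main` ([tap_series()]) and
#'   `envelope` (the main block's envelope).
#' @export
run_paired_blocks <- function(config, tapper, condition,
                              subject_id = "s1", block_index = 1) {
  stopifnot(inherits(config, "session_config"), inherits(tapper, "tapper"))
  bid <- sprintf("%s_%s_b%d", subject_id, condition, block_index)
  drift <- config$mu_drift_sd %||% 0
  drifted <- function(tag) {
    if (drift == 0) return(tapper)
    set.seed(derive_seed(config$seed, subject_id, condition, block_index,
                         tag, "drift"))
    tp <- tapper
    tp$mu <- max(tapper$mu + stats::rnorm(1, 0, drift), tapper$mu / 2)
    tp
  }
  est_spec <- condition_frequency(1, "estimation",
                                  duration = config$estimation_duration,
                                  sample_rate = config$phase_rate,
                                  p_min = config$p_min, p_max = config$p_max)
  est_env <- make_envelope(est_spec)
  estimation <- simulate_rhythmic_block(
    drifted("est"), est_env, config$estimation_duration,
    seed = derive_seed(config$seed, subject_id, condition, block_index,
                       "est"),
    subject_id = subject_id, block_id = paste0(bid, "_est"),
    condition = "estimation")
  if (length(drop_times(estimation)) < 2)
    stop("run_paired_blocks: estimation block too sparse to estimate a rate",
         call. = FALSE)
  rate <- estimate_preferred_rate(estimation)
  spec <- condition_frequency(rate, condition,
                              duration = config$main_duration,
                              sample_rate = config$phase_rate,
                              p_min = config$p_min, p_max = config$p_max,
                              lambda = config$lambda,
                              pulse_width = config$pulse_width)
  env <- make_envelope(spec, seed = derive_seed(config$seed, subject_id,
                                                condition, block_index,
                                                "env"))
  main_seed <- derive_seed(config$seed, subject_id, condition, block_index,
                           "main")
  main_tapper <- drifted("main")
  main <- if (config$task == "rhythmic") {
    simulate_rhythmic_block(main_tapper, env, config$main_duration,
                            seed = main_seed, subject_id = subject_id,
                            block_id = bid, condition = condition)
  } else {
    simulate_single_tap_trials(main_tapper, env, config$n_trials,
                               seed = main_seed, subject_id = subject_id,
                               block_id = bid, condition = condition)
  }
  list(estimation = estimation, main = main, envelope = env)
}

#' Simulate a full cohort
#'
#' Draws each subject's preferred interval around `mu_mean`, assigns a
#' uniform preferred phase, and runs every condition's block pairs through
#' [run_paired_blocks()]. The single-tap task uses a longer envelope sized
#' to the trial schedule.
#'
#' @param config a [session_config()].
#' @return list with `taps` (list of main-block [tap_series()]),
#'   `envelopes` (named by `block_id`), `estimations` (list of estimation
#'   blocks) and `subjects` (data.frame of drawn tapper parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "session_config"))
  taps <- list()
  envelopes <- list()
  estimations <- list()
  subj_rows <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", i)
    set.seed(derive_seed(config$seed, sid, "tapper"))
    mu <- stats::rnorm(1, config$mu_mean, config$mu_sd)
    mu <- max(mu, 0.3)
    psi <- stats::runif(1, 0, 360)
    subj_rows[[i]] <- data.frame(subject_id = sid, mu = mu, psi = psi,
                                 sigma = config$sigma)
    for (cond in config$conditions) {
      tp <- tapper(mu = mu, sigma = config$sigma,
                   kappa = kappa_for(config$kappa, cond), psi = psi,
                   sigma_tempo = config$sigma_tempo %||% 0,
                   lapse_prob = config$lapse_prob %||% 0)
      for (b in seq_len(config$blocks_per_condition)) {
        cfg_b <- config
        if (config$task == "single_tap")
          cfg_b$main_duration <- ceiling(config$n_trials * 5) + 30
        pb <- run_paired_blocks(cfg_b, tp, cond, subject_id = sid,
                                block_index = b)
        taps[[pb$main$block_id]] <- pb$main
        envelopes[[pb$main$block_id]] <- pb$envelope
        estimations[[pb$estimation$block_id]] <- pb$estimation
      }
    }
  }
  list(taps = taps, envelopes = envelopes, estimations = estimations,
       subjects = do.call(rbind, subj_rows))
}

# per-condition coupling lookup: scalar kappa applies everywhere, a named
# vector is indexed by condition (absent names mean uncoupled)
kappa_for <- function(kappa, condition) {
  if (length(kappa) == 1 && is.null(names(kappa))) return(kappa)
  if (condition %in% names(kappa)) return(unname(kappa[[condition]]))
  0
}

#' Write tap events to a tab-delimited file
#'
#' One event per row; columns `subject_id`, `block_id`, `condition`,
#' `task`, `event`, `time_s` (seconds, microsecond precision), plus
#' `aware` (questionnaire flag). A single file may hold many blocks.
#'
#' @param series a [tap_series()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tap_events <- function(series, path) {
  if (inherits(series, "tap_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    if (nrow(s$events) == 0) return(NULL)
    data.frame(subject_id = s$subject_id, block_id = s$block_id,
               condition = s$condition, task = s$task,
               event = s$events$event,
               time_s = sprintf("%.6f", s$events$time),
               duration_s = sprintf("%.6f", s$duration),
               aware = s$aware)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(subject_id = character(0), block_id = character(0),
                     condition = character(0), task = character(0),
                     event = character(0), time_s = character(0),
                     duration_s = character(0), aware = logical(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tap events from a tab-delimited file
#'
#' Validates the dialect (header, required columns) and each block's event
#' structure (strictly increasing times, lift/drop alternation starting
#' with a lift); violations are reported with the offending file rows.
#'
#' @param path input path, as written by [write_tap_events()].
#' @return named list of [tap_series()], keyed by `block_id`.
#' @export
read_tap_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "block_id", "condition", "task", "event",
                "time_s")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("read_tap_events: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(list())
  df$time_s <- as.numeric(df$time_s)
  df$.row <- seq_len(nrow(df)) + 1L  # file line numbers (header = line 1)
  out <- list()
  for (bid in unique(df$block_id)) {
    sub <- df[df$block_id == bid, ]
    dur <- if ("duration_s" %in% names(sub))
      as.numeric(sub$duration_s[1]) else max(sub$time_s)
    aware <- if ("aware" %in% names(sub)) isTRUE(as.logical(sub$aware[1]))
             else FALSE
    bad_t <- which(diff(sub$time_s) <= 0)
    if (length(bad_t) > 0)
      stop(sprintf("read_tap_events: non-increasing time in block '%s' at ",
                   bid), "file row(s) ",
           paste(sub$.row[bad_t + 1], collapse = ", "), call. = FALSE)
    expected <- rep(c("lift", "drop"), length.out = nrow(sub))
    bad_e <- which(sub$event != expected)
    if (length(bad_e) > 0)
      stop(sprintf("read_tap_events: lift/drop alternation violated in block '%s' at file row(s) ", bid),
           paste(sub$.row[bad_e], collapse = ", "), call. = FALSE)
    out[[bid]] <- tap_series(
      data.frame(event = sub$event, time = sub$time_s),
      subject_id = sub$subject_id[1], block_id = bid,
      condition = sub$condition[1], task = sub$task[1],
      duration = dur, aware = aware)
  }
  out
}
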