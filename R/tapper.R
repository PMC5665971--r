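#' Define a synthetic tapper
#'
#' A minimal generative model of self-paced tapping with optional phase
#' coupling to a modulation envelope. The tapper has a preferred inter-tap
#' interval `mu` (seconds), Gaussian interval noise `sigma`, a coupling
#' strength `kappa` (dimensionless, 0 = free-running) and a preferred phase
#' `psi` (degrees). Rhythmic blocks follow the standard first-order
#' phase-correction update of the sensorimotor-synchronization literature:
#' \deqn{t_{n+1} = t_n + \mu + \epsilon_n -
#'   \frac{\kappa\mu}{360}\,\mathrm{wrap}(\phi(t_n) - \psi)}
#' with \eqn{\epsilon_n \sim N(0, \sigma^2)} and wrap() mapping to
#' (-180, 180]. Its kappa = 0 and sigma = 0 limits are analytically
#' checkable, and detuning the envelope away from 1/mu abolishes locking,
#' mirroring the physics of entrainment.
#'
#' With the defaults (`sigma_tempo = 0`, `lapse_prob = 0`) the model is the
#' minimal white-noise phase-correction tapper, whose limits are
#' analytically checkable. Two optional realism features, used by the
#' cohort generator ([session_config()]), emulate robust properties of real
#' un-paced tapping: `sigma_tempo` adds the slow tempo wander of the
#' two-level timing model (a random walk on the local interval, clamped to
#' `[mu/2, 2*mu]`), and `lapse_prob` adds occasional pauses (an extra delay
#' of 0.5-1.5 intervals) emulating hesitations and missed contacts.
#'
#' @param mu preferred inter-tap interval, seconds (> 0).
#' @param sigma white interval noise standard deviation, seconds (>= 0).
#' @param kappa coupling strength, dimensionless (>= 0).
#' @param psi preferred phase, degrees in [0, 360).
#' @param sigma_tempo tempo-drift random-walk step per tap, seconds (>= 0).
#' @param lapse_prob per-tap probability of a pause (in [0, 1)).
#' @param lapse_range pause duration range, in units of `mu`.
#' @return an object of class `"tapper"`.
#' @export
tapper <- function(mu, sigma = 0.05, kappa = 0, psi = 0,
                   sigma_tempo = 0, lapse_prob = 0,
                   lapse_range = c(0.5, 1.5)) {
  stopifnot(is.numeric(mu), mu > 0, sigma >= 0, kappa >= 0,
            sigma_tempo >= 0, lapse_prob >= 0, lapse_prob < 1)
  psi <- wrap360(psi)
  structure(list(mu = mu, sigma = sigma, kappa = kappa, psi = psi,
                 sigma_tempo = sigma_tempo, lapse_prob = lapse_prob,
                 lapse_range = lapse_range),
            class = "tapper")
}

#' Construct a tap-event series
#'
#' Validated container for timestamped lift/drop events of one block.
#' Events must be strictly increasing in time, alternate beginning with a
#' lift, and lie within `[0, duration]`.
#'
#' @param events data.frame with columns `event` ("lift"/"drop") and `time`
#'   (seconds).
#' @param subject_id,block_id labels.
#' @param condition one of "estimation", "near", "far", "baseline".
#' @param task "rhythmic" or "single_tap".
#' @param duration block duration, seconds.
#' @param aware questionnaire metadata flag: did this subject report
#'   noticing the noise modulation?
#' @return an object of class `"tap_series"`.
#' @export
tap_series <- function(events, subject_id, block_id,
                       condition = c("estimation", "near", "far", "baseline"),
                       task = c("rhythmic", "single_tap"),
                       duration, aware = FALSE) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  stopifnot(is.data.frame(events), all(c("event", "time") %in% names(events)))
  ev <- as.character(events$event)
  tt <- as.numeric(events$time)
  if (nrow(events) > 0) {
    if (any(diff(tt) <= 0))
      stop("tap_series: event times must be strictly increasing",
           call. = FALSE)
    expected <- rep(c("lift", "drop"), length.out = length(ev))
    if (!all(ev == expected))
      stop("tap_series: lifts and drops must alternate, beginning with lift",
           call. = FALSE)
    if (any(tt < 0 | tt > duration))
      stop("tap_series: event times must lie within [0, duration]",
           call. = FALSE)
  }
  structure(list(events = data.frame(event = ev, time = tt),
                 subject_id = subject_id, block_id = block_id,
                 condition = condition, task = task,
                 duration = duration, aware = isTRUE(aware)),
            class = "tap_series")
}

#' Drop times of a tap series
#'
#' The analysis uses finger drops (the moment the finger touches down).
#'
#' @param series a [tap_series()].
#' @return numeric vector of drop times, seconds.
#' @export
drop_times <- function(series) {
  stopifnot(inherits(series, "tap_series"))
  series$events$time[series$events$event == "drop"]
}

#' @export
print.tap_series <- function(x, ...) {
  cat(sprintf("<tap_series> %s/%s %s %s: %d taps over %gs%s\n",
              x$subject_id, x$block_id, x$condition, x$task,
              sum(x$events$event == "drop"), x$duration,
              if (x$aware) " [aware]" else ""))
  invisible(x)
}

#' Simulate a rhythmic tapping block
#'
#' Generates drop times from the tapper's phase-correction update against
#' the envelope's instantaneous phase (free-running when `kappa = 0` or when
#' the envelope has no defined phase, as in unmodulated estimation blocks).
#' Each drop is preceded by a lift at a fixed offset. If the coupling drives
#' an interval non-positive it is floored at `mu/4` with a warning.
#'
#' @param tapper a [tapper()].
#' @param envelope a [make_envelope()] result; the block's stimulus.
#' @param duration block duration, seconds (`<=` envelope duration).
#' @param seed integer seed.
#' @param lift_offset lift-to-drop offset, seconds.
#' @param subject_id,block_id,condition,aware labels attached to the
#'   returned series; `condition` defaults to "estimation" for constant
#'   envelopes and "near" otherwise.
#' @return a `"tap_series"` with `task = "rhythmic"`.
#' @export
simulate_rhythmic_block <- function(tapper, envelope, duration, seed,
                                    lift_offset = 0.1,
                                    subject_id = "sim", block_id = "sim",
                                    condition = NULL, aware = FALSE) {
  stopifnot(inherits(tapper, "tapper"), inherits(envelope, "envelope"))
  if (duration > envelope$spec$duration + 1e-9)
    stop("simulate_rhythmic_block: duration exceeds envelope duration",
         call. = FALSE)
  set.seed(seed)
  mu <- tapper$mu
  coupled <- tapper$kappa > 0 && envelope$phase_defined
  drops <- numeric(0)
  mu_n <- mu                       # local tempo, drifts as a random walk
  t <- mu_n + stats::rnorm(1, 0, tapper$sigma)
  t <- max(t, mu / 4)
  floored <- FALSE
  while (t < duration) {
    drops <- c(drops, t)
    mu_n <- mu_n + stats::rnorm(1, 0, tapper$sigma_tempo)
    mu_n <- min(max(mu_n, mu / 2), 2 * mu)
    dt <- mu_n + stats::rnorm(1, 0, tapper$sigma)
    if (coupled) {
      err <- wrap180(phase_at(envelope, t) - tapper$psi)
      dt <- dt - (tapper$kappa * mu / 360) * err
    }
    if (tapper$lapse_prob > 0 && stats::runif(1) < tapper$lapse_prob)
      dt <- dt + stats::runif(1, tapper$lapse_range[1],
                              tapper$lapse_range[2]) * mu
    if (dt < mu / 4) {
      dt <- mu / 4
      floored <- TRUE
    }
    t <- t + dt
  }
  if (floored)
    warning("simulate_rhythmic_block: coupling forced short intervals; ",
            "floored at mu/4")
  events <- interleave_lifts(drops, lift_offset)
  if (is.null(condition))
    condition <- if (envelope$spec$kind == "constant") "estimation" else "near"
  tap_series(events, subject_id = subject_id, block_id = block_id,
             condition = condition, task = "rhythmic", duration = duration,
             aware = aware)
}

# lift precedes each drop by `offset`, clamped to stay after the previous
# drop and non-negative
interleave_lifts <- function(drops, offset) {
  n <- length(drops)
  if (n == 0) return(data.frame(event = character(0), time = numeric(0)))
  lifts <- drops - offset
  prev <- c(0, drops[-n])
  lifts <- pmax(lifts, prev + 1e-4 * (prev > 0), 0)
  data.frame(event = rep(c("lift", "drop"), n),
             time = as.vector(rbind(lifts, drops)))
}

# Best & Fisher (1979) von Mises sampler; mean direction mu_deg (degrees),
# concentration kap. Returns degrees in [0, 360).
rvonmises_deg <- function(n, mu_deg, kap) {
  if (kap < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kap^2)
  b <- (a - sqrt(2 * a)) / (2 * kap)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kap * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        theta <- sign(u[3] - 0.5) * acos(f)
        out[i] <- theta * 180 / pi
        break
      }
    }
  }
  wrap360(out + mu_deg)
}

#' Simulate single-tap trials
#'
#' Each trial shows a 2 s instruction, then the tapper waits a self-chosen
#' exponential delay (floor 0.2 s, mean `delay_mean`) and taps once. With
#' mixing weight \eqn{w = \kappa/(1+\kappa)} the tap is phase-nudged: its
#' phase is drawn from a von Mises distribution about `psi` with
#' concentration `2*kappa` and the tap time shifted (within one modulation
#' cycle) to realize that phase; with weight `1 - w` the tap keeps its
#' uniform-phase candidate time. Nudging requires an invertible phase map
#' and so applies only to sine envelopes; against aperiodic or constant
#' envelopes taps are never nudged. Trials are separated by a jittered
#' inter-trial interval of about 1 s.
#'
#' @param tapper a [tapper()]; `kappa` and `psi` control the nudging.
#' @param envelope a [make_envelope()] result, long enough to hold all
#'   trials.
#' @param n_trials number of trials (>= 1); one lift-drop pair each.
#' @param delay_mean mean self-chosen delay, seconds.
#' @param seed integer seed.
#' @param lift_offset lift-to-drop offset, seconds.
#' @param subject_id,block_id,condition,aware labels attached to the
#'   returned series.
#' @return a `"tap_series"` with `task = "single_tap"`.
#' @export
simulate_single_tap_trials <- function(tapper, envelope, n_trials,
                                       delay_mean = 1, seed,
                                       lift_offset = 0.1,
                                       subject_id = "sim", block_id = "sim",
                                       condition = "near", aware = FALSE) {
  stopifnot(inherits(tapper, "tapper"), inherits(envelope, "envelope"),
            n_trials >= 1)
  set.seed(seed)
  spec <- envelope$spec
  w <- tapper$kappa / (1 + tapper$kappa)
  nudgeable <- spec$kind == "sine" && tapper$kappa > 0
  taps <- numeric(n_trials)
  t0 <- 0
  for (i in seq_len(n_trials)) {
    delay <- 0.2 + stats::rexp(1, 1 / max(delay_mean - 0.2, 0.05))
    cand <- t0 + 2 + delay
    if (nudgeable && stats::runif(1) < w) {
      target <- rvonmises_deg(1, tapper$psi, 2 * tapper$kappa)
      cur <- wrap360(360 * spec$frequency * cand)
      cand <- cand + wrap180(target - cur) / (360 * spec$frequency)
    }
    if (cand >= spec$duration)
      stop("simulate_single_tap_trials: envelope shorter than the trial ",
           "schedule", call. = FALSE)
    taps[i] <- cand
    t0 <- cand + stats::runif(1, 0.8, 1.2)  # jittered ITI ~ 1 s
  }
  taps <- sort(taps)
  events <- interleave_lifts(taps, lift_offset)
  tap_series(events, subject_id = subject_id, block_id = block_id,
             condition = condition, task = "single_tap",
             duration = spec$duration, aware = aware)
}

#' Estimate the preferred tapping rate
#'
#' Reciprocal of the mean inter-drop interval of a rhythmic block; used on
#' the unmodulated estimation block to set the condition's modulation
#' frequency.
#'
#' @param series a rhythmic [tap_series()] with at least 2 drops.
#' @return rate in Hz.
#' @export
estimate_preferred_rate <- function(series) {
  stopifnot(inherits(series, "tap_series"))
  if (series$task != "rhythmic")
    stop("estimate_preferred_rate: series must be a rhythmic block",
         call. = FALSE)
  d <- drop_times(series)
  if (length(d) < 2)
    stop("estimate_preferred_rate: need at least 2 drops", call. = FALSE)
  1 / mean(diff(d))
}

#' Modulation frequency rule for a condition
#'
#' Maps a subject's preferred tapping rate to the condition's envelope
#' specification: `near` modulates at the preferred rate, `far` at 1.5
#' times it, `baseline` is the aperiodic Poisson-pulse envelope (mean
#' interval `lambda`), and `estimation` is unmodulated (constant).
#'
#' @param rate preferred tapping rate, Hz (> 0).
#' @param condition one of "near", "far", "baseline", "estimation".
#' @param duration,sample_rate,p_min,p_max,lambda,pulse_width passed through
#'   to [envelope_spec()].
#' @return an `"envelope_spec"`.
#' @export
condition_frequency <- function(rate,
                                condition = c("near", "far", "baseline",
                                              "estimation"),
                                duration = 60, sample_rate = 22050,
                                p_min = 0.05, p_max = 0.1,
                                lambda = 1, pulse_width = 0.35) {
  condition <- match.arg(condition)
  if (!is.numeric(rate) || rate <= 0)
    stop("condition_frequency: rate must be > 0", call. = FALSE)
  switch(condition,
    near = envelope_spec("sine", frequency = rate, p_min = p_min,
                         p_max = p_max, duration = duration,
                         sample_rate = sample_rate),
    far = envelope_spec("sine", frequency = 1.5 * rate, p_min = p_min,
                        p_max = p_max, duration = duration,
                        sample_rate = sample_rate),
    baseline = envelope_spec("poisson_pulse", p_min = p_min, p_max = p_max,
                             lambda = lambda, pulse_width = pulse_width,
                             duration = duration, sample_rate = sample_rate),
    estimation = envelope_spec("constant", p_min = p_min, p_max = p_max,
                               duration = duration,
                               sample_rate = sample_rate))
}
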