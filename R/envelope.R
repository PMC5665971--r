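#' Specify a spike-probability modulation envelope
#'
#' The envelope sets the per-sample probability that the noise generator emits
#' a signed spike. Three kinds are supported: a sinusoidal modulation between
#' `p_min` and `p_max` (the periodic conditions), a random series of
#' rectangular pulses with Poisson-distributed inter-pulse intervals (the
#' aperiodic baseline condition), and a constant envelope at the midpoint
#' probability (unmodulated noise, used in estimation blocks).
#'
#' The phase convention is fixed throughout the package: 0 degrees at the
#' envelope maximum (`p = p_max`, the loudness peak), so a sinusoidal envelope
#' is \eqn{p(t) = p_{mid} + (p_{max}-p_{min})/2 \cdot \cos(2\pi f t)}.
#'
#' @param kind one of `"sine"`, `"poisson_pulse"`, `"constant"`.
#' @param frequency modulation frequency in Hz (sine only).
#' @param p_min,p_max spike probability bounds per sample, `0 <= p_min <=
#'   p_max <= 1`.
#' @param lambda mean of the Poisson inter-pulse interval distribution in
#'   seconds (poisson_pulse only).
#' @param pulse_width pulse duration in seconds (poisson_pulse only).
#' @param duration envelope duration in seconds; `duration * sample_rate`
#'   must be a whole number of samples.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `"envelope_spec"`.
#' @export
envelope_spec <- function(kind = c("sine", "poisson_pulse", "constant"),
                          frequency = NULL,
                          p_min = 0.05, p_max = 0.1,
                          lambda = 1, pulse_width = 0.35,
                          duration = 60, sample_rate = 22050) {
  kind <- match.arg(kind)
  if (!is.numeric(p_min) || !is.numeric(p_max) ||
      p_min < 0 || p_max > 1 || p_min > p_max)
    stop("envelope_spec: p_min/p_max must satisfy 0 <= p_min <= p_max <= 1",
         call. = FALSE)
  if (kind == "sine") {
    if (is.null(frequency) || !is.numeric(frequency) || frequency <= 0)
      stop("envelope_spec: frequency must be > 0 for kind = 'sine'",
           call. = FALSE)
  }
  if (kind == "poisson_pulse") {
    if (!is.numeric(lambda) || lambda <= 0)
      stop("envelope_spec: lambda must be > 0 for kind = 'poisson_pulse'",
           call. = FALSE)
    if (!is.numeric(pulse_width) || pulse_width <= 0)
      stop("envelope_spec: pulse_width must be > 0 for kind = 'poisson_pulse'",
           call. = FALSE)
  }
  if (duration <= 0)
    stop("envelope_spec: duration must be > 0", call. = FALSE)
  if (sample_rate <= 0)
    stop("envelope_spec: sample_rate must be > 0", call. = FALSE)
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-8)
    stop("envelope_spec: duration * sample_rate must be a whole number ",
         "of samples", call. = FALSE)
  structure(list(kind = kind,
                 frequency = if (kind == "sine") frequency else NULL,
                 p_min = p_min, p_max = p_max,
                 lambda = lambda, pulse_width = pulse_width,
                 duration = duration, sample_rate = sample_rate,
                 phase_origin = "0 deg at envelope maximum"),
            class = "envelope_spec")
}

#' Realize an envelope from its specification
#'
#' Builds the per-sample spike-probability series `p` and its instantaneous
#' phase track. Sine envelopes carry the analytic phase
#' \eqn{360 f t \bmod 360}. Poisson-pulse envelopes place rectangular
#' excursions from `p_min` to `p_max` at onsets whose inter-onset intervals
#' are drawn from a Poisson distribution with mean `lambda` (zero draws are
#' redrawn so pulses never merge); their phase is the analytic-signal
#' (Hilbert) instantaneous phase of the mean-removed `p` series after
#' band-limiting to 0.55-1.9 times the mean pulse rate, with 0 degrees at
#' local envelope maxima (see the source comment for why the band limit is
#' needed). Constant envelopes have `p` fixed at
#' `(p_min + p_max)/2` and no defined phase.
#'
#' @param spec an [envelope_spec()].
#' @param seed integer seed; required for `kind = "poisson_pulse"`.
#' @return an object of class `"envelope"` with elements `spec`, `p`,
#'   `phase` (degrees in [0, 360), or `NA` when undefined) and
#'   `phase_defined`.
#' @export
make_envelope <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "envelope_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  p_mid <- (spec$p_min + spec$p_max) / 2
  half <- (spec$p_max - spec$p_min) / 2
  if (spec$kind == "sine") {
    phase <- wrap360(360 * spec$frequency * t)
    p <- p_mid + half * cospi(phase / 180)
    phase_defined <- TRUE
  } else if (spec$kind == "poisson_pulse") {
    if (is.null(seed))
      stop("make_envelope: seed is required for kind = 'poisson_pulse'",
           call. = FALSE)
    onsets <- poisson_pulse_onsets(spec$duration, spec$lambda, seed)
    p <- rep(spec$p_min, n)
    for (on in onsets) {
      i0 <- floor(on * spec$sample_rate) + 1
      i1 <- min(n, ceiling((on + spec$pulse_width) * spec$sample_rate))
      if (i0 <= n) p[i0:i1] <- spec$p_max
    }
    # Hilbert phase of the band-limited, mean-removed pulse train. The raw
    # train is broadband: its analytic phase dwells near 180 deg between
    # pulses and sweeps during them, so taps uniform in time would sample a
    # non-uniform phase and the baseline U would not be calibrated against
    # uniformity. Restricting to [0.55, 1.9] x the mean pulse rate before the
    # transform gives a rotating phase whose time marginal is uniform.
    f0 <- (1 - exp(-spec$lambda)) / spec$lambda  # zero-truncated pulse rate
    phase <- analytic_phase(bandlimit(p - mean(p), spec$sample_rate,
                                      0.55 * f0, 1.9 * f0))
    phase_defined <- TRUE
  } else {
    p <- rep(p_mid, n)
    phase <- rep(NA_real_, n)
    phase_defined <- FALSE
  }
  structure(list(spec = spec, p = p, phase = phase,
                 phase_defined = phase_defined, seed = seed),
            class = "envelope")
}

#' Draw baseline inter-pulse intervals
#'
#' The aperiodic baseline envelope spaces its pulses by intervals drawn from
#' a Poisson distribution with mean `lambda` (in seconds). This sampler
#' exposes that interval distribution directly, e.g. for moment checks.
#'
#' @param n number of intervals.
#' @param lambda Poisson mean, seconds.
#' @param seed integer seed.
#' @return integer-valued numeric vector of length `n`.
#' @export
baseline_intervals <- function(n, lambda = 1, seed) {
  stopifnot(n >= 1, lambda > 0)
  set.seed(seed)
  stats::rpois(n, lambda)
}

# FFT brick-wall band-pass: zero all components outside [f_lo, f_hi]
bandlimit <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# Pulse onset times for the baseline envelope. Intervals are Poisson(lambda)
# with zero draws redrawn, so consecutive pulses never coincide; onsets
# accumulate from time 0 until the block duration is filled.
poisson_pulse_onsets <- function(duration, lambda, seed) {
  set.seed(seed)
  onsets <- numeric(0)
  t <- 0
  repeat {
    iv <- stats::rpois(1, lambda)
    while (iv == 0) iv <- stats::rpois(1, lambda)
    t <- t + iv
    if (t >= duration) break
    onsets <- c(onsets, t)
  }
  onsets
}

#' Envelope phase at given times
#'
#' For sine envelopes the phase is analytic, \eqn{360 f t \bmod 360}, exact
#' at any time. For Poisson-pulse envelopes the stored Hilbert phase track is
#' looked up at the nearest sample. Constant envelopes have no defined phase.
#'
#' @param envelope an [make_envelope()] result.
#' @param times numeric vector of times in seconds, each within
#'   `[0, duration)`.
#' @return numeric vector of phases in degrees, `[0, 360)`.
#' @export
phase_at <- function(envelope, times) {
  stopifnot(inherits(envelope, "envelope"))
  spec <- envelope$spec
  bad <- times < 0 | times >= spec$duration
  if (any(bad))
    stop(sprintf("phase_at: time %.6g s outside [0, %g)",
                 times[which(bad)[1]], spec$duration), call. = FALSE)
  if (!envelope$phase_defined)
    stop("phase_at: envelope has no defined phase (constant kind)",
         call. = FALSE)
  if (spec$kind == "sine") {
    wrap360(360 * spec$frequency * times)
  } else {
    idx <- pmin(length(envelope$phase),
                pmax(1, round(times * spec$sample_rate) + 1))
    envelope$phase[idx]
  }
}

#' @export
print.envelope <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<envelope> kind=%s duration=%gs rate=%gHz", s$kind,
              s$duration, s$sample_rate))
  if (s$kind == "sine") cat(sprintf(" f=%gHz", s$frequency))
  cat(sprintf(" p=[%g, %g]\n", s$p_min, s$p_max))
  invisible(x)
}
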