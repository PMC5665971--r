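#' Generate a signed spike train under an envelope
#'
#' Each sample independently emits a spike with the envelope's per-sample
#' probability; given a spike, its sign is +1 or -1 with equal probability.
#' Deterministic for a fixed seed.
#'
#' @param envelope an [make_envelope()] result.
#' @param seed integer seed.
#' @return an object of class `"spike_train"` with elements `values`
#'   (per-sample series in {-1, 0, +1}), `spec` and `seed`.
#' @export
generate_spike_train <- function(envelope, seed) {
  stopifnot(inherits(envelope, "envelope"))
  set.seed(seed)
  n <- length(envelope$p)
  spike <- stats::runif(n) < envelope$p
  sgn <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  values <- integer(n)
  values[spike] <- sgn[spike]
  structure(list(values = values, spec = envelope$spec, seed = seed),
            class = "spike_train")
}

#' Impose a 1/f^beta power spectrum on a spike train
#'
#' Reweights the amplitude spectrum by \eqn{f^{-\beta/2}} (so the power
#' spectral density is multiplied by \eqn{f^{-\beta}}), leaves the
#' zero-frequency term untouched, preserves the input's spectral phase, and
#' peak-normalizes the result to `[-1, 1]`. With `beta = 1.5` this softens
#' the white spike train toward pink noise.
#'
#' @param train a [generate_spike_train()] result.
#' @param beta spectral exponent, `>= 0`.
#' @return an object of class `"waveform"` with elements `samples`, `beta`
#'   and `sample_rate`.
#' @export
shape_spectrum <- function(train, beta = 1.5) {
  stopifnot(inherits(train, "spike_train"), beta >= 0)
  x <- as.numeric(train$values)
  n <- length(x)
  if (n == 0) stop("shape_spectrum: empty spike train", call. = FALSE)
  fs <- train$spec$sample_rate
  if (all(x == 0)) {
    warning("shape_spectrum: all-zero spike train; returning zero waveform")
    return(structure(list(samples = x, beta = beta, sample_rate = fs),
                     class = "waveform"))
  }
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n       # two-sided frequency axis
  w <- c(1, f[-1]^(-beta / 2))       # DC untouched
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE) / n)
  y <- y / max(abs(y))
  structure(list(samples = y, beta = beta, sample_rate = fs),
            class = "waveform")
}

#' Estimate the spectral exponent of a waveform
#'
#' Welch-averaged periodogram (Hann window, 50% overlap) followed by a
#' linear regression of log10 power on log10 frequency over `band`. Returns
#' the exponent beta, i.e. minus the fitted log-log slope.
#'
#' @param waveform a [shape_spectrum()] result, or any numeric vector with a
#'   `sample_rate` argument.
#' @param band frequency band (Hz) over which to regress; default 1-1000 Hz.
#' @param seg_length samples per Welch segment.
#' @param sample_rate only used when `waveform` is a bare numeric vector.
#' @return estimated beta (dimensionless).
#' @export
estimate_spectral_exponent <- function(waveform, band = c(1, 1000),
                                       seg_length = 2^14,
                                       sample_rate = NULL) {
  if (inherits(waveform, "waveform")) {
    x <- waveform$samples
    fs <- waveform$sample_rate
  } else {
    x <- as.numeric(waveform)
    if (is.null(sample_rate))
      stop("estimate_spectral_exponent: sample_rate needed for a bare vector",
           call. = FALSE)
    fs <- sample_rate
  }
  ps <- welch_psd(x, fs, seg_length)
  keep <- ps$freq >= band[1] & ps$freq <= band[2] & ps$power > 0
  fit <- stats::lm(log10(power) ~ log10(freq), data = ps[keep, ])
  -unname(stats::coef(fit)[2])
}

# Welch PSD: Hann-windowed segments, 50% overlap, averaged one-sided
# periodograms (DC and Nyquist dropped).
welch_psd <- function(x, fs, seg_length) {
  n <- length(x)
  seg_length <- min(seg_length, n)
  step <- max(1, floor(seg_length / 2))
  starts <- seq(1, n - seg_length + 1, by = step)
  win <- 0.5 - 0.5 * cospi(2 * (0:(seg_length - 1)) / seg_length)
  norm <- sum(win^2)
  nf <- floor(seg_length / 2)
  acc <- numeric(nf - 1)
  for (s in starts) {
    seg <- x[s:(s + seg_length - 1)] * win
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[2:nf])^2) / norm
  }
  data.frame(freq = (1:(nf - 1)) * fs / seg_length,
             power = acc / length(starts))
}

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' @param waveform a [shape_spectrum()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_wav <- function(waveform, path) {
  stopifnot(inherits(waveform, "waveform"))
  pcm <- as.integer(round(pmax(-1, pmin(1, waveform$samples)) * 32767))
  n <- length(pcm)
  fs <- as.integer(round(waveform$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write the ground-truth phase track sidecar for an envelope
#'
#' Tab-delimited text with columns `sample_index`, `time_s`, `p`,
#' `phase_deg`; the companion to each synthesized stimulus file.
#'
#' @param envelope an [make_envelope()] result.
#' @param path output file path.
#' @param every write every `every`-th sample (1 = all samples).
#' @return `path`, invisibly.
#' @export
write_phase_track <- function(envelope, path, every = 1L) {
  stopifnot(inherits(envelope, "envelope"))
  n <- length(envelope$p)
  idx <- seq(1L, n, by = as.integer(every))
  df <- data.frame(sample_index = idx - 1L,
                   time_s = (idx - 1L) / envelope$spec$sample_rate,
                   p = envelope$p[idx],
                   phase_deg = envelope$phase[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
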