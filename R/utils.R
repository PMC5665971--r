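#' Wrap angles into (-180, 180]
#'
#' Maps angular differences onto the signed half-circle, the form needed by
#' the phase-correction update and by circular summaries.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
wrap180 <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Reduce angles to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Circular mean direction
#'
#' Direction of the vector sum of unit phasors, in degrees.
#'
#' @param angles numeric vector of angles in degrees.
#' @return mean direction in [0, 360); `NA` if the resultant length is
#'   numerically zero (the mean direction is then undefined).
#' @export
circ_mean <- function(angles) {
  s <- sum(sinpi(angles / 180))
  c <- sum(cospi(angles / 180))
  if (sqrt(s^2 + c^2) < 1e-12 * length(angles)) return(NA_real_)
  m <- wrap360(atan2(s, c) * 180 / pi)
  if (m >= 360 - 1e-9) 0 else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: a small polynomial string hash of the
# master seed and a sequence of keys, kept below 2^31 so it is a valid R seed.
# Same (master, keys...) always yields the same sub-seed.
derive_seed <- function(master, ...) {
  keys <- paste(c(master, ...), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(keys)) h <- (h * 131 + b) %% 2147483629
  as.integer(h %% 2147483647)
}

# Instantaneous phase of the analytic signal (FFT construction): phase 0 deg
# at local maxima of a cosine-like input, increasing through the cycle.
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  wrap360(atan2(Im(z), Re(z)) * 180 / pi)
}
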