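# Shared numerical helpers: analytic signal, band-pass filtering, argument
# checks. The phase convention used throughout the package: model signals use
# arg(z) directly; real-valued signals use the angle of the analytic signal
# obtained after (zero-phase) band-pass filtering.

#' Analytic signal via the frequency domain
#'
#' Computes the analytic signal `x + i*H(x)` of each row of a real matrix
#' (channels x samples) or of a single numeric vector, using the FFT
#' construction: positive frequencies doubled, negative frequencies zeroed,
#' DC (and Nyquist for even length) kept.
#'
#' @param x numeric vector, or matrix with one channel per row.
#' @return complex object of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, analytic_signal))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  stopifnot(n >= 2L, all(is.finite(x)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) so that phase relationships -- on which wPLI and
#' SMI depend -- are preserved.
#'
#' @param x numeric vector or channels-x-samples matrix.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, pass band in Hz; must lie inside (0, fs/2).
#' @param order Butterworth order (default 4).
#' @return filtered object of the same shape.
#' @export
band_pass <- function(x, fs, band, order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2)
    stop("band must lie strictly below the Nyquist frequency fs/2 = ", fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  flt <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, flt))
    dimnames(out) <- dimnames(x)
    out
  } else {
    flt(x)
  }
}

#' Phase-randomized surrogate of a signal
#'
#' Randomizes the Fourier phases of each channel independently while keeping
#' the amplitude spectrum, destroying cross-channel phase relationships but
#' preserving each channel's power spectrum (and hence autocorrelation).
#'
#' @param x numeric vector or channels-x-samples matrix.
#' @return surrogate of the same shape.
#' @export
phase_randomize <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, phase_randomize))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  X <- fft(x)
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  if (half >= 1L) {
    ph <- runif(half, 0, 2 * pi)
    idx <- 2L:(half + 1L)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2L - idx] <- Conj(X[idx])
  }
  Re(fft(X, inverse = TRUE) / n)
}

# internal: scalar argument checks
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single number in (%g, %g)", name, lo, hi))
  x
}
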