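# Functional network configuration: weighted phase lag index connectivity
# (robust to zero-lag volume conduction), degree extraction from binarized
# epoch-wise wPLI matrices, and the degree-amplitude topographic similarity
# S^amp that flags hub-dominant configurations.

#' Weighted phase lag index between two signals
#'
#' `wPLI = |E[Im(C_xy)]| / E[|Im(C_xy)|]` where `C_xy` is the
#' sample-by-sample cross-spectrum of the analytic signals. Equals 1 when
#' one signal's phase always leads (or always lags) the other's, 0 when the
#' lead/lag relationship is perfectly balanced, and 0 by convention when the
#' imaginary cross-spectrum vanishes identically (no lagged interaction).
#'
#' @param x,y equal-length numeric vectors (band-limited), or complex
#'   analytic signals.
#' @return scalar in `[0, 1]`.
#' @export
wpli_pair <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (!is.complex(x)) x <- analytic_signal(x)
  if (!is.complex(y)) y <- analytic_signal(y)
  im <- Im(x * Conj(y))
  den <- mean(abs(im))
  if (den == 0) return(0)
  abs(mean(im)) / den
}

#' Epoch-wise wPLI matrices, binarization, and node degrees
#'
#' Splits the recording into epochs (default 30 s with 5 s overlap),
#' computes the full wPLI matrix per epoch, binarizes each matrix at the top
#' `top_fraction` of off-diagonal pair values (ties resolved by stable pair
#' index order), and reports the per-channel degree averaged over epochs --
#' a functional stand-in for structural node degree.
#'
#' @param signals n_channels x n_samples matrix, already band-passed.
#' @param fs sampling rate in Hz.
#' @param epoch,epoch_overlap epoch length and overlap in seconds.
#' @param top_fraction fraction of pairs retained by binarization.
#' @return object of class `wpli_matrix`: list with `epoch_matrices`,
#'   `binarized`, `epoch_degrees` (channels x epochs), and `degrees`
#'   (mean over epochs).
#' @export
wpli_degrees <- function(signals, fs, epoch = 30, epoch_overlap = 5,
                         top_fraction = 0.30) {
  stopifnot(is.matrix(signals), nrow(signals) >= 2L, epoch > epoch_overlap)
  check_fraction(top_fraction, "top_fraction")
  starts <- windowize(ncol(signals), fs, epoch, epoch_overlap)
  if (length(starts) == 0L)
    stop("recording shorter than one full epoch of ", epoch, " s")
  len <- attr(starts, "window_samples")
  n <- nrow(signals)
  analytic <- analytic_signal(signals)
  epoch_matrices <- binarized <- vector("list", length(starts))
  epoch_degrees <- matrix(0, n, length(starts))
  for (e in seq_along(starts)) {
    idx <- starts[e]:(starts[e] + len - 1L)
    w <- matrix(0, n, n)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      w[a, b] <- w[b, a] <- wpli_pair(analytic[a, idx], analytic[b, idx])
    bin <- binarize_top(w, top_fraction)
    epoch_matrices[[e]] <- w
    binarized[[e]] <- bin
    epoch_degrees[, e] <- rowSums(bin)
  }
  structure(list(epoch_matrices = epoch_matrices, binarized = binarized,
                 epoch_degrees = epoch_degrees,
                 degrees = rowMeans(epoch_degrees)),
            class = "wpli_matrix")
}

# retain exactly ceiling(top_fraction * n_pairs) strongest off-diagonal
# pairs; ties broken by ascending pair index (stable, reproducible)
binarize_top <- function(w, top_fraction) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  n_keep <- ceiling(top_fraction * length(ut))
  ord <- order(-w[ut], ut)  # strength desc, then stable pair index
  keep <- ut[ord[seq_len(n_keep)]]
  bin <- matrix(FALSE, n, n)
  bin[keep] <- TRUE
  bin | t(bin)
}

#' Degree-amplitude topographic similarity S^amp
#'
#' Instantaneous Spearman rank correlation between a fixed per-unit degree
#' vector (structural degrees in the model; time-averaged wPLI degrees for
#' sensor signals) and the instantaneous amplitude vector, evaluated at
#' every sample and averaged per temporal window. Positive values indicate
#' hub-dominant configurations. A constant degree vector has no ranking and
#' yields `NA` throughout.
#'
#' @param degrees per-unit degree vector.
#' @param amplitudes n_units x n_samples matrix of instantaneous amplitudes
#'   (|z| for model runs, analytic-signal modulus for sensor signals).
#' @param windows window start indices from [windowize()]; `NULL` for the
#'   instantaneous series only.
#' @return object of class `topography_result`: list with `s_amp_t`
#'   (per-sample correlation in `[-1, 1]`) and `window_means`.
#' @export
s_amp <- function(degrees, amplitudes, windows = NULL) {
  stopifnot(is.matrix(amplitudes), length(degrees) == nrow(amplitudes))
  st <- inst_spearman_cpp(amplitudes, rank(degrees))
  wm <- NULL
  if (!is.null(windows)) {
    len <- attr(windows, "window_samples")
    if (is.null(len)) stop("`windows` must come from windowize()")
    wm <- vapply(windows, function(s0) mean(st[s0:(s0 + len - 1L)]),
                 numeric(1))
  }
  structure(list(s_amp_t = st, window_means = wm),
            class = "topography_result")
}
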