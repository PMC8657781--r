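# Global synchronization metrics: Kuramoto order parameter, pair correlation
# function (the criticality proxy), window-wise susceptibility, temporal
# window construction and classification, and the SMI-chi joint histogram.

#' Kuramoto order parameter of a multichannel phase series
#'
#' `r(t) e^{i psi(t)} = mean_j e^{i theta_j(t)}`: `r(t) = 1` when all units
#' share a phase, 0 for uniformly spread phases.
#'
#' @param phases n_units x n_samples matrix of phases (radians).
#' @param fs sampling rate in Hz (carried along for windowing).
#' @return object of class `sync_series`: list with `r`, `psi`, `fs`,
#'   `n_units`.
#' @export
order_parameter <- function(phases, fs = NA_real_) {
  stopifnot(is.matrix(phases), all(is.finite(phases)))
  if (nrow(phases) < 2L) stop("order parameter needs at least 2 units")
  m <- colMeans(exp(1i * phases))
  structure(list(r = Mod(m), psi = Arg(m), fs = fs, n_units = nrow(phases)),
            class = "sync_series")
}

#' Pair correlation function
#'
#' `PCF = N * (<r^2> - <r>^2)`: the number of units times the temporal
#' (population) variance of the order parameter. Maximal synchronization
#' fluctuation -- and hence maximal PCF -- marks the critical regime.
#'
#' @param sync a `sync_series`, or a numeric `r(t)` vector if `n_units`
#'   is given.
#' @param n_units number of units (taken from `sync` when omitted).
#' @return scalar PCF.
#' @export
pcf <- function(sync, n_units = NULL) {
  r <- if (inherits(sync, "sync_series")) sync$r else sync
  n_units <- n_units %||% sync$n_units
  stopifnot(length(r) >= 2L, is.numeric(n_units))
  n_units * (mean(r^2) - mean(r)^2)
}

#' Window-wise network susceptibility
#'
#' `chi = N * (<r^2> - <r>^2) / <r>` over the samples of one window: the PCF
#' of the window normalized by its mean synchronization. Proxies the
#' network's responsiveness to external perturbation; undefined (NA) when
#' `<r> = 0`.
#'
#' @param r_window numeric vector of order-parameter samples in the window.
#' @param n_units number of units.
#' @return scalar susceptibility (>= 0), or `NA` if the window mean is 0.
#' @export
susceptibility <- function(r_window, n_units) {
  stopifnot(length(r_window) >= 1L, is.numeric(n_units))
  m <- mean(r_window)
  if (m == 0) return(NA_real_)
  n_units * (mean(r_window^2) - m^2) / m
}

#' Construct half-open temporal windows
#'
#' Tiles `1..series_length` with windows of `window` seconds advancing by
#' `window - overlap`; a final partial window is dropped. Start indices are
#' 1-based; window `w` covers samples `starts[w] .. starts[w] + len - 1`.
#'
#' @param series_length number of samples.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds.
#' @param overlap overlap between consecutive windows in seconds
#'   (`overlap < window`).
#' @return integer vector of start indices with attributes
#'   `window_samples` and `stride_samples`; empty when the series is
#'   shorter than one window.
#' @export
windowize <- function(series_length, fs, window = 0.25, overlap = 0.05) {
  stopifnot(series_length >= 1L, fs > 0, window > overlap, overlap >= 0)
  len <- round(window * fs)
  stride <- round((window - overlap) * fs)
  stopifnot(len >= 1L, stride >= 1L)
  if (len > series_length)
    return(structure(integer(0), window_samples = len,
                     stride_samples = stride))
  starts <- seq.int(1L, series_length - len + 1L, by = stride)
  structure(as.integer(starts), window_samples = as.integer(len),
            stride_samples = as.integer(stride))
}

#' Classify windows by mean synchronization
#'
#' `fixed` mode uses absolute thresholds (model convention: low below 0.3,
#' high above 0.5). `pooled` mode uses `mean -/+ 0.5 * sd` of `R` pooled
#' over all windows/subjects/states (the sensor-signal convention); pass the
#' pooled statistics explicitly so the same thresholds apply across
#' conditions.
#'
#' @param R_values numeric vector of per-window mean synchronization.
#' @param mode `"fixed"` or `"pooled"`.
#' @param fixed_low,fixed_high fixed-mode thresholds (`fixed_low <
#'   fixed_high`).
#' @param pooled_stats length-2 numeric `c(mean, sd)` for pooled mode.
#' @return factor with levels `low`, `neither`, `high`.
#' @export
classify_windows <- function(R_values, mode = c("fixed", "pooled"),
                             fixed_low = 0.3, fixed_high = 0.5,
                             pooled_stats = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(fixed_low < fixed_high)
    lo <- fixed_low
    hi <- fixed_high
  } else {
    stopifnot(is.numeric(pooled_stats), length(pooled_stats) == 2L,
              pooled_stats[2] >= 0)
    lo <- pooled_stats[1] - 0.5 * pooled_stats[2]
    hi <- pooled_stats[1] + 0.5 * pooled_stats[2]
  }
  cls <- ifelse(R_values < lo, "low",
                ifelse(R_values > hi, "high", "neither"))
  cls <- factor(cls, levels = c("low", "neither", "high"))
  if (length(R_values) > 0L && !any(cls == "low") && !any(cls == "high"))
    warning("thresholds eliminated both low and high classes")
  cls
}

#' Joint histogram of SMI and susceptibility
#'
#' Counts (SMI, chi) window pairs over fixed-width bins anchored at 0 with
#' right-open edges; bin widths follow the standard visualization convention
#' (0.02 for SMI, 0.1 for chi).
#'
#' @param smi_values,chi_values equal-length numeric vectors.
#' @param smi_bin,chi_bin bin widths.
#' @return list with `counts` (SMI bins x chi bins), `smi_edges`,
#'   `chi_edges`; empty input gives an empty grid.
#' @export
joint_histogram <- function(smi_values, chi_values, smi_bin = 0.02,
                            chi_bin = 0.1) {
  stopifnot(length(smi_values) == length(chi_values))
  keep <- is.finite(smi_values) & is.finite(chi_values)
  smi_values <- smi_values[keep]
  chi_values <- chi_values[keep]
  if (length(smi_values) == 0L)
    return(list(counts = matrix(0L, 0L, 0L), smi_edges = numeric(0),
                chi_edges = numeric(0)))
  stopifnot(all(smi_values >= 0), all(chi_values >= 0))
  ns <- floor(max(smi_values) / smi_bin) + 1L
  nc <- floor(max(chi_values) / chi_bin) + 1L
  is_ <- pmin(floor(smi_values / smi_bin) + 1L, ns)
  ic <- pmin(floor(chi_values / chi_bin) + 1L, nc)
  counts <- matrix(0L, ns, nc)
  for (t in seq_along(is_))
    counts[is_[t], ic[t]] <- counts[is_[t], ic[t]] + 1L
  list(counts = counts,
       smi_edges = seq(0, by = smi_bin, length.out = ns + 1L),
       chi_edges = seq(0, by = chi_bin, length.out = nc + 1L))
}

#' Maximum resolved frequency of the ordinal transform
#'
#' A pattern of `m` samples separated by `tau` steps spans `m * tau` samples
#' and therefore resolves oscillations up to `fs / (m * tau)` Hz (11.9 Hz at
#' the 500 Hz / m = 3 / tau = 14 defaults, matching the 4-12 Hz band of
#' interest).
#'
#' @param fs sampling rate in Hz.
#' @param m symbol size.
#' @param tau symbol lag in samples.
#' @return frequency in Hz.
#' @export
max_resolved_frequency <- function(fs = 500, m = 3, tau = 14) {
  stopifnot(fs > 0, m >= 2, tau >= 1)
  fs / (m * tau)
}
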