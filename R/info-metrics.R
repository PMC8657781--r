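# Ordinal-pattern symbolization and symbolic mutual information (SMI). Two
# signals are mapped to sequences over the m! rank-order patterns of m
# samples separated by tau_sym steps; SMI is the plug-in mutual information
# of the joint symbol distribution, normalized by log(m!) so it lives in
# [0, 1]. Being rank-based, SMI is invariant under strictly monotone
# transforms of either raw signal.

#' Symbolization configuration
#'
#' Defaults: pattern length `m = 3` (6 ordinal patterns), lag `tau_sym = 14`
#' samples at the 500 Hz reference rate (a 28 ms separation, resolving up to
#' ~11.9 Hz), 20 phase-randomized surrogates, significance level 0.01 for
#' the surrogate filter.
#'
#' @param m symbol size (>= 2).
#' @param tau_sym symbol lag in samples (>= 1), quoted at `ref_fs`.
#' @param n_surrogates surrogate count for the significance filter.
#' @param alpha_sig significance level of the per-pair rank-sum test.
#' @param ref_fs sampling rate (Hz) at which `tau_sym` is quoted; for data
#'   at a different rate the lag is rescaled to keep the temporal
#'   separation fixed (see [rescale_symbol_lag()]).
#' @return object of class `symbolic_config`.
#' @export
symbolic_config <- function(m = 3L, tau_sym = 14L, n_surrogates = 20L,
                            alpha_sig = 0.01, ref_fs = 500) {
  m <- check_count(m, "m", min = 2L)
  tau_sym <- check_count(tau_sym, "tau_sym", min = 1L)
  n_surrogates <- check_count(n_surrogates, "n_surrogates", min = 1L)
  check_fraction(alpha_sig, "alpha_sig")
  structure(list(m = m, tau_sym = tau_sym, n_surrogates = n_surrogates,
                 alpha_sig = alpha_sig, ref_fs = ref_fs),
            class = "symbolic_config")
}

#' Rescale the symbol lag to a new sampling rate
#'
#' Keeps the temporal separation `tau_sym / ref_fs` fixed: at 250 Hz the
#' 28 ms separation becomes 7 samples.
#'
#' @param cfg a `symbolic_config`.
#' @param fs target sampling rate in Hz.
#' @return the config with `tau_sym` (and `ref_fs`) adjusted.
#' @export
rescale_symbol_lag <- function(cfg, fs) {
  stopifnot(inherits(cfg, "symbolic_config"), fs > 0)
  if (fs == cfg$ref_fs) return(cfg)
  tau <- max(1L, as.integer(round(cfg$tau_sym * fs / cfg$ref_fs)))
  cfg$tau_sym <- tau
  cfg$ref_fs <- fs
  cfg
}

#' Ordinal-pattern symbolization of a signal
#'
#' Maps position `t` to the rank-order pattern of
#' `(x_t, x_{t+tau}, ..., x_{t+(m-1)tau})`, encoded as an integer in
#' `0 .. m!-1` (Lehmer code). Rank ties are broken by temporal order: the
#' earlier sample ranks lower.
#'
#' @param x numeric vector of length at least `(m-1)*tau_sym + 1`.
#' @param cfg a `symbolic_config`.
#' @return integer vector of symbols, length `length(x) - (m-1)*tau_sym`.
#' @export
symbolize <- function(x, cfg = symbolic_config()) {
  stopifnot(is.numeric(x), inherits(cfg, "symbolic_config"))
  span <- (cfg$m - 1L) * cfg$tau_sym
  if (length(x) < span + 1L)
    stop("signal shorter than one ordinal pattern span ((m-1)*tau + 1 = ",
         span + 1L, " samples)")
  drop(symbolize_cpp(matrix(x, nrow = 1L), cfg$m, cfg$tau_sym))
}

#' Symbolic mutual information between two symbol sequences
#'
#' Plug-in mutual information of the empirical joint symbol distribution,
#' normalized by `log(m!)`; equals 1 for identical sequences with a uniform
#' symbol distribution and tends to 0 for long independent sequences.
#'
#' @param xs,ys equal-length integer symbol sequences over `0 .. m!-1`.
#' @param m symbol size used to produce the sequences.
#' @return scalar SMI in `[0, 1]`.
#' @export
smi <- function(xs, ys, m = 3L) {
  if (length(xs) != length(ys)) stop("symbol sequences differ in length")
  smi_cpp(as.integer(xs), as.integer(ys), as.integer(m))
}

#' Per-window pairwise SMI with optional surrogate filtering
#'
#' Symbolizes every channel once, then computes SMI for all unordered channel
#' pairs in each temporal window. With `surrogate_filter = TRUE`, each pair's
#' real per-window SMI values are compared (two-sided Wilcoxon rank-sum test
#' across windows) with the pooled per-window SMI values of
#' `cfg$n_surrogates` phase-randomized surrogate datasets; pairs that do not
#' reach `cfg$alpha_sig` are excluded from the per-window mean. A window
#' whose pairs are all filtered out reports `NA`.
#'
#' @param signals n_channels x n_samples numeric matrix.
#' @param starts window start indices (1-based) from [windowize()], with the
#'   `window_samples` attribute.
#' @param cfg a `symbolic_config` (already at the data's sampling rate).
#' @param surrogate_filter apply the significance filter (the sensor-signal
#'   convention; off for model runs).
#' @param keep_matrices return the per-window pairwise SMI matrices.
#' @return object of class `smi_result`: list with `mean_smi` (per window),
#'   `significant_mask` (n x n logical, all-TRUE without filtering),
#'   `retained_fraction`, and optionally `matrices`.
#' @export
pairwise_smi <- function(signals, starts, cfg = symbolic_config(),
                         surrogate_filter = FALSE, keep_matrices = FALSE) {
  stopifnot(is.matrix(signals), nrow(signals) >= 2L,
            inherits(cfg, "symbolic_config"))
  wlen <- attr(starts, "window_samples")
  if (is.null(wlen)) stop("`starts` must come from windowize()")
  span <- (cfg$m - 1L) * cfg$tau_sym
  if (wlen <= span)
    stop("window shorter than one full ordinal pattern span")
  n <- nrow(signals)
  n_sym <- wlen - span

  pair_smi_windows <- function(x) {
    sym <- symbolize_cpp(x, cfg$m, cfg$tau_sym)
    vapply(seq_along(starts), function(w)
      smi_matrix_cpp(sym, starts[w] - 1L, n_sym, cfg$m),
      matrix(0, n, n))
  }

  real_sw <- pair_smi_windows(signals)  # n x n x n_windows
  mask <- matrix(TRUE, n, n)
  if (surrogate_filter) {
    surr <- lapply(seq_len(cfg$n_surrogates), function(s)
      pair_smi_windows(phase_randomize(signals)))
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      real_vals <- real_sw[a, b, ]
      surr_vals <- unlist(lapply(surr, function(sv) sv[a, b, ]))
      p <- suppressWarnings(
        wilcox.test(real_vals, surr_vals, exact = FALSE)$p.value)
      mask[a, b] <- mask[b, a] <- is.finite(p) && p < cfg$alpha_sig
    }
  }
  diag(mask) <- FALSE
  upper <- upper.tri(mask)
  keep <- mask & upper
  mean_smi <- vapply(seq_along(starts), function(w) {
    v <- real_sw[, , w][keep]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  out <- list(mean_smi = mean_smi, significant_mask = mask,
              retained_fraction = sum(mask[upper]) / sum(upper))
  if (keep_matrices) out$matrices <- real_sw
  structure(out, class = "smi_result")
}
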