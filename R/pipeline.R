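# End-to-end experiment drivers: the model-side sweep with per-cell
# window-metric correlations (criticality localization by PCF maximum), the
# sensor-signal pipeline with pooled-threshold window classification and
# low/high comparisons, and a simple amplitude-based artifact rejector.

# 3-point moving average with truncated edges; argmax-stabilizer for noisy
# seed-averaged curves over a parameter grid
smooth_3pt <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1L, i - 1L):min(n, i + 1L)], na.rm = TRUE), numeric(1))
}

#' Model experiment: sweep, window metrics, and R-metric correlations
#'
#' Runs [sl_sweep()] with window metrics and summarizes each (lambda, K)
#' cell by its mean synchronization, PCF, and the Spearman correlations of
#' window-wise `R` with `SMI`, `chi`, and `S^amp` across all windows of all
#' seeds. The critical `K` for each `lambda` is the PCF maximum across the
#' K grid (seed-averaged).
#'
#' @param conn a `connectome`.
#' @param lam_grid,K_grid parameter grids.
#' @param n_seeds simulations per cell (fresh natural frequencies per seed).
#' @param params_base an `sl_params` (its `lam`/`K` are overridden).
#' @param seed master seed.
#' @param window,overlap window geometry in seconds.
#' @param cfg a `symbolic_config`.
#' @return list with `summary` (per cell: lam, K, mean_R, pcf, rho_R_smi,
#'   rho_R_chi, rho_R_samp), `windows` (all window metrics), `critical`
#'   (per lambda: the PCF-maximal K). Because the seed-averaged PCF is a
#'   noisy estimate of a smooth curve, its maximum over K is located on a
#'   3-point moving average (truncated at the grid edges) rather than on
#'   the raw per-cell values.
#' @export
run_model_experiment <- function(conn, lam_grid, K_grid, n_seeds,
                                 params_base, seed = 1L, window = 0.25,
                                 overlap = 0.05, cfg = symbolic_config()) {
  sw <- sl_sweep(conn, lam_grid, K_grid, n_seeds, params_base, seed = seed,
                 window_metrics = TRUE, window = window, overlap = overlap,
                 cfg = cfg)
  cells <- unique(sw$summary[, c("lam", "K")])
  rho <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok], method = "spearman")
  }
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    lam <- cells$lam[i]
    K <- cells$K[i]
    s <- sw$summary[sw$summary$lam == lam & sw$summary$K == K, ]
    w <- sw$windows[sw$windows$lam == lam & sw$windows$K == K, ]
    data.frame(lam = lam, K = K,
               mean_R = mean(s$mean_R, na.rm = TRUE),
               pcf = mean(s$pcf, na.rm = TRUE),
               rho_R_smi = rho(w$R, w$smi),
               rho_R_chi = rho(w$R, w$chi),
               rho_R_samp = rho(w$R, w$s_amp),
               n_windows = nrow(w))
  }))
  critical <- do.call(rbind, lapply(unique(summary$lam), function(lam) {
    s <- summary[summary$lam == lam, ]
    s <- s[order(s$K), ]
    sm <- smooth_3pt(s$pcf)
    data.frame(lam = lam, K_critical = s$K[which.max(sm)],
               pcf_max = max(s$pcf, na.rm = TRUE))
  }))
  list(summary = summary, windows = sw$windows, critical = critical)
}

#' Sensor-signal experiment: windowed metrics and low/high comparisons
#'
#' For each condition: common-average re-reference, zero-phase band-pass,
#' analytic phases and amplitudes, per-window `R`, `chi`, mean pairwise SMI
#' (with optional surrogate filtering), and `S^amp` against wPLI-derived
#' degrees (taken from `baseline` and reused for the other conditions,
#' mirroring a baseline-referenced design). Windows of all conditions are
#' pooled for the `mean +/- 0.5 sd` classification; each condition then gets
#' rank-sum comparisons of SMI and chi between its low- and high-R windows,
#' its PCF, and an SMI-chi joint histogram.
#'
#' @param signals_by_condition named list of n_channels x n_samples
#'   matrices.
#' @param fs sampling rate in Hz.
#' @param band pass band in Hz.
#' @param window,overlap window geometry in seconds.
#' @param cfg a `symbolic_config` (quoted at its `ref_fs`; rescaled to
#'   `fs`).
#' @param surrogate_filter apply the SMI surrogate significance filter.
#' @param baseline name of the condition whose wPLI degrees are used for
#'   `S^amp` in all conditions (default: the first).
#' @param epoch,epoch_overlap wPLI epoch geometry in seconds.
#' @param rereference apply common-average re-referencing before filtering.
#' @return list with `windows` (tidy per-window table: condition,
#'   window_start, R, smi, chi, s_amp, sync_class), `pooled_stats`,
#'   `condition_summary` (PCF, rank-sum p-values, class medians), and
#'   `histograms` (per condition, split by class).
#' @export
run_signal_experiment <- function(signals_by_condition, fs, band = c(4, 12),
                                  window = 0.25, overlap = 0.05,
                                  cfg = symbolic_config(),
                                  surrogate_filter = TRUE,
                                  baseline = NULL, epoch = 30,
                                  epoch_overlap = 5, rereference = TRUE) {
  stopifnot(is.list(signals_by_condition),
            length(signals_by_condition) >= 1L)
  if (is.null(names(signals_by_condition)))
    names(signals_by_condition) <- paste0("cond", seq_along(signals_by_condition))
  baseline <- baseline %||% names(signals_by_condition)[1L]
  stopifnot(baseline %in% names(signals_by_condition))
  cfg <- rescale_symbol_lag(cfg, fs)

  prep <- lapply(signals_by_condition, function(x) {
    stopifnot(is.matrix(x), nrow(x) >= 2L)
    if (rereference) x <- sweep(x, 2L, colMeans(x))
    band_pass(x, fs, band)
  })
  degrees <- tryCatch(
    wpli_degrees(prep[[baseline]], fs, epoch, epoch_overlap)$degrees,
    error = function(e) NULL)  # recordings shorter than one epoch

  per_cond <- lapply(names(prep), function(nm) {
    x <- prep[[nm]]
    an <- analytic_signal(x)
    phases <- Arg(an)
    amps <- Mod(an)
    sync <- order_parameter(phases, fs = fs)
    starts <- windowize(ncol(x), fs, window, overlap)
    if (length(starts) == 0L) return(NULL)
    len <- attr(starts, "window_samples")
    sm <- pairwise_smi(x, starts, cfg, surrogate_filter = surrogate_filter)
    samp_w <- if (is.null(degrees)) rep(NA_real_, length(starts)) else
      s_amp(degrees, amps, starts)$window_means
    R <- chi <- numeric(length(starts))
    for (w in seq_along(starts)) {
      rw <- sync$r[starts[w]:(starts[w] + len - 1L)]
      R[w] <- mean(rw)
      chi[w] <- susceptibility(rw, nrow(x))
    }
    list(df = data.frame(condition = nm, window_start = starts, R = R,
                         smi = sm$mean_smi, chi = chi, s_amp = samp_w),
         pcf = pcf(sync))
  })
  names(per_cond) <- names(prep)
  per_cond <- Filter(Negate(is.null), per_cond)
  if (length(per_cond) == 0L) stop("no condition yielded a full window")

  windows <- do.call(rbind, lapply(per_cond, `[[`, "df"))
  rownames(windows) <- NULL
  pooled_stats <- c(mean = mean(windows$R), sd = sd(windows$R))
  windows$sync_class <- classify_windows(windows$R, "pooled",
                                         pooled_stats = pooled_stats)

  cmp <- function(v, cls) {
    lo <- v[cls == "low" & is.finite(v)]
    hi <- v[cls == "high" & is.finite(v)]
    if (length(lo) < 2L || length(hi) < 2L)
      return(list(p = NA_real_, med_low = median(lo), med_high = median(hi)))
    list(p = suppressWarnings(wilcox.test(lo, hi, exact = FALSE)$p.value),
         med_low = median(lo), med_high = median(hi))
  }
  condition_summary <- do.call(rbind, lapply(names(per_cond), function(nm) {
    w <- windows[windows$condition == nm, ]
    s <- cmp(w$smi, w$sync_class)
    x <- cmp(w$chi, w$sync_class)
    data.frame(condition = nm, pcf = per_cond[[nm]]$pcf,
               n_low = sum(w$sync_class == "low"),
               n_high = sum(w$sync_class == "high"),
               smi_med_low = s$med_low, smi_med_high = s$med_high,
               smi_p = s$p, chi_med_low = x$med_low,
               chi_med_high = x$med_high, chi_p = x$p)
  }))
  histograms <- lapply(names(per_cond), function(nm) {
    w <- windows[windows$condition == nm, ]
    list(low = joint_histogram(w$smi[w$sync_class == "low"],
                               w$chi[w$sync_class == "low"]),
         high = joint_histogram(w$smi[w$sync_class == "high"],
                                w$chi[w$sync_class == "high"]))
  })
  names(histograms) <- names(per_cond)
  list(windows = windows, pooled_stats = pooled_stats,
       condition_summary = condition_summary, histograms = histograms,
       degrees = degrees)
}

#' Amplitude-based artifact rejection
#'
#' Scans the recording in consecutive non-overlapping blocks of
#' `reject_span` seconds and excises every block in which any sample
#' exceeds `amp_threshold` or any channel's within-block standard deviation
#' exceeds `sd_threshold` (thresholds in the signal's units, conventionally
#' microvolts). Warns when more than half the data is removed.
#'
#' @param signals n_channels x n_samples matrix.
#' @param fs sampling rate in Hz.
#' @param sd_threshold per-channel block standard-deviation threshold.
#' @param amp_threshold absolute amplitude threshold.
#' @param reject_span block length in seconds.
#' @return list with `signals` (cleaned, columns removed), `rejected`
#'   (data.frame of removed spans: start/end sample, start/end seconds),
#'   `fraction_removed`.
#' @export
artifact_reject <- function(signals, fs, sd_threshold = 100,
                            amp_threshold = 300, reject_span = 0.2) {
  stopifnot(is.matrix(signals), fs > 0, sd_threshold > 0,
            amp_threshold > 0, reject_span > 0)
  blk <- max(2L, round(reject_span * fs))
  n <- ncol(signals)
  starts <- seq.int(1L, n, by = blk)
  bad <- logical(n)
  rej <- list()
  for (s0 in starts) {
    idx <- s0:min(s0 + blk - 1L, n)
    seg <- signals[, idx, drop = FALSE]
    if (max(abs(seg)) > amp_threshold ||
        any(apply(seg, 1L, sd) > sd_threshold)) {
      bad[idx] <- TRUE
      rej[[length(rej) + 1L]] <- data.frame(
        start_sample = idx[1L], end_sample = idx[length(idx)],
        start_s = (idx[1L] - 1L) / fs, end_s = idx[length(idx)] / fs)
    }
  }
  frac <- mean(bad)
  if (frac > 0.5)
    warning(sprintf("artifact rejection removed %.0f%% of the data",
                    100 * frac))
  list(signals = signals[, !bad, drop = FALSE],
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(start_sample = integer(0), end_sample = integer(0),
                    start_s = numeric(0), end_s = numeric(0)),
       fraction_removed = frac)
}
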