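# Delay-coupled Stuart-Landau network simulation. Each node is the normal
# form of a supercritical Hopf bifurcation (limit cycle of radius sqrt(lambda)
# for lambda > 0, damped focus for lambda < 0); nodes interact through the
# structural adjacency with axonal conduction delays tau_jk = D_jk / speed.

#' Stuart-Landau simulation parameters
#'
#' Collects the homogeneous model parameters. Defaults reflect the standard
#' operating point for EEG-band simulations: diffusive coupling weight
#' `alpha = 0.5` (between purely chemical-synapse-like input at 0 and gap-
#' junction-like exchange at 1), complex Gaussian noise of sd `beta = 0.05`,
#' conduction speed 7 m/s (so mm distances give ms delays), integration step
#' 1 ms decimated to a 500 Hz output rate, 15 s of transient discarded and
#' 60 s retained for analysis.
#'
#' @param lam bifurcation parameter, homogeneous across nodes.
#' @param K coupling strength, homogeneous across edges.
#' @param alpha diffusive-coupling weight in `[0, 1]`.
#' @param beta noise standard deviation (per component, per sqrt(step)).
#' @param speed axonal conduction speed in m/s.
#' @param dt integration step in seconds.
#' @param fs_out output sampling rate in Hz (`fs_out <= 1/dt`).
#' @param t_saturate discarded transient, seconds.
#' @param t_analyze retained duration, seconds.
#' @return object of class `sl_params`.
#' @export
sl_params <- function(lam, K, alpha = 0.5, beta = 0.05, speed = 7,
                      dt = 1e-3, fs_out = 500, t_saturate = 15,
                      t_analyze = 60) {
  stopifnot(is.finite(lam), is.finite(K), alpha >= 0, alpha <= 1,
            beta >= 0, speed > 0, dt > 0, fs_out > 0, fs_out <= 1 / dt,
            t_saturate >= 0, t_analyze > 0)
  decim <- 1 / (dt * fs_out)
  if (abs(decim - round(decim)) > 1e-9)
    stop("1/(dt * fs_out) must be an integer decimation factor")
  structure(list(lam = lam, K = K, alpha = alpha, beta = beta, speed = speed,
                 dt = dt, fs_out = fs_out, t_saturate = t_saturate,
                 t_analyze = t_analyze, decim = as.integer(round(decim))),
            class = "sl_params")
}

#' Simulate a delay-coupled Stuart-Landau network
#'
#' Integrates
#' `dz_j = (lam + i*omega_j - |z_j|^2) z_j dt +
#'   K * sum_k A_jk (z_k(t - tau_jk) - alpha z_j) dt + beta dW_j`
#' with the two-stage Stratonovich-Heun predictor-corrector at step `dt`,
#' then discards `t_saturate` seconds and decimates to `fs_out`. Delays
#' `tau_jk = D_jk / speed` are rounded to the nearest integration step;
#' history before t = 0 holds the random initial state (drawn uniformly on
#' the complex unit disc under `seed`).
#'
#' @param conn a `connectome` (see [generate_connectome()]).
#' @param freqs a `frequency_set` of length `conn$n_nodes`.
#' @param params an `sl_params`.
#' @param seed integer seed for the initial state and the noise path.
#' @return object of class `sl_sim`: list with complex `z`
#'   (n_nodes x n_samples at `fs_out`), `phases`, `amplitudes`, `fs`,
#'   `params`, `freqs`, `seed`.
#' @export
sl_simulate <- function(conn, freqs, params, seed) {
  stopifnot(inherits(conn, "connectome"), inherits(freqs, "frequency_set"),
            inherits(params, "sl_params"))
  if (length(freqs$omega) != conn$n_nodes)
    stop("frequency set length must equal the number of nodes")
  seed <- check_count(seed, "seed", min = 0L)
  p <- params
  delay_steps <- matrix(as.integer(round(conn$distances * 1e-3 /
                                           p$speed / p$dt)),
                        conn$n_nodes, conn$n_nodes)
  n_steps <- as.integer(round((p$t_saturate + p$t_analyze) / p$dt))
  n_discard <- as.integer(round(p$t_saturate / p$dt))
  set.seed(seed)
  rad <- sqrt(runif(conn$n_nodes))
  ang <- runif(conn$n_nodes, 0, 2 * pi)
  z0 <- complex(modulus = rad, argument = ang)
  z <- sl_integrate_cpp(conn$adjacency, delay_steps, freqs$omega,
                        p$lam, p$K, p$alpha, p$beta, p$dt,
                        n_steps, n_discard, p$decim, z0)
  structure(list(z = z, phases = Arg(z), amplitudes = Mod(z),
                 fs = p$fs_out, params = p, freqs = freqs, seed = seed),
            class = "sl_sim")
}

#' @export
print.sl_sim <- function(x, ...) {
  cat(sprintf("Stuart-Landau simulation: %d nodes, %.1f s at %g Hz (lambda = %g, K = %g)\n",
              nrow(x$z), ncol(x$z) / x$fs, x$fs, x$params$lam, x$params$K))
  invisible(x)
}

#' Sweep the (lambda, K) parameter plane
#'
#' Runs [sl_simulate()] for every grid cell and seed (a fresh frequency set
#' per seed) and summarizes each run by its time-averaged order parameter
#' `mean_R` and pair correlation function `pcf`. Window-level metrics (R,
#' SMI, chi, S^amp per window) are attached when `window_metrics = TRUE`.
#' Divergent cells are reported with their coordinates and skipped; the
#' sweep continues.
#'
#' @param conn a `connectome`.
#' @param lam_grid,K_grid numeric grids (non-empty).
#' @param n_seeds simulations per cell.
#' @param params_base an `sl_params` whose `lam`/`K` are overridden per cell.
#' @param seed master seed; per-run seeds and frequency seeds derive from it.
#' @param window_metrics compute per-window R/SMI/chi/S^amp per run.
#' @param window,overlap window length and overlap in seconds (model
#'   convention: 250 ms windows, 50 ms overlap).
#' @param cfg a `symbolic_config` for the SMI stage.
#' @param mean_hz,sd_hz natural-frequency distribution per seed.
#' @return list with `summary` (data.frame: lam, K, seed, mean_R, pcf,
#'   diverged) and, if requested, `windows` (data.frame: lam, K, seed,
#'   window_start, R, smi, chi, s_amp).
#' @export
sl_sweep <- function(conn, lam_grid, K_grid, n_seeds, params_base, seed = 1L,
                     window_metrics = FALSE, window = 0.25, overlap = 0.05,
                     cfg = symbolic_config(), mean_hz = 10, sd_hz = 0.5) {
  stopifnot(length(lam_grid) >= 1L, length(K_grid) >= 1L, n_seeds >= 1L)
  set.seed(check_count(seed, "seed", min = 0L))
  run_seeds <- matrix(sample.int(2^30, 2L * n_seeds), nrow = 2L)
  degrees <- rowSums(conn$adjacency)

  summ <- list()
  wins <- list()
  for (i in seq_len(n_seeds)) {
    freqs <- generate_frequencies(conn$n_nodes, mean_hz, sd_hz,
                                  seed = run_seeds[1L, i])
    for (lam in lam_grid) for (K in K_grid) {
      p <- params_base
      p$lam <- lam
      p$K <- K
      sim <- tryCatch(
        sl_simulate(conn, freqs, p, seed = run_seeds[2L, i]),
        error = function(e) e
      )
      if (inherits(sim, "error")) {
        warning(sprintf("divergent cell lam=%g K=%g seed=%d: %s",
                        lam, K, run_seeds[2L, i], conditionMessage(sim)))
        summ[[length(summ) + 1L]] <- data.frame(
          lam = lam, K = K, seed = run_seeds[2L, i],
          mean_R = NA_real_, pcf = NA_real_, diverged = TRUE)
        next
      }
      sync <- order_parameter(sim$phases, fs = sim$fs)
      summ[[length(summ) + 1L]] <- data.frame(
        lam = lam, K = K, seed = run_seeds[2L, i],
        mean_R = mean(sync$r), pcf = pcf(sync), diverged = FALSE)
      if (window_metrics) {
        wm <- window_metrics(sim, sync, degrees, window, overlap, cfg)
        wm$lam <- lam
        wm$K <- K
        wm$seed <- run_seeds[2L, i]
        wins[[length(wins) + 1L]] <- wm
      }
    }
  }
  out <- list(summary = do.call(rbind, summ))
  if (window_metrics) out$windows <- do.call(rbind, wins)
  out
}

#' Per-window synchronization, information, and topography metrics of a run
#'
#' For each temporal window: mean order parameter `R`, susceptibility `chi`,
#' mean pairwise SMI over all node pairs (no surrogate filtering, the model
#' convention), and mean instantaneous degree-amplitude Spearman correlation
#' `s_amp` (structural degrees).
#'
#' @param sim an `sl_sim`.
#' @param sync optional precomputed [order_parameter()] series.
#' @param degrees per-node degree vector; for model runs pass the
#'   structural degrees `rowSums(conn$adjacency)`.
#' @param window,overlap seconds.
#' @param cfg a `symbolic_config`.
#' @return data.frame with `window_start` (1-based sample index), `R`,
#'   `chi`, `smi`, `s_amp`.
#' @export
window_metrics <- function(sim, sync = NULL, degrees, window = 0.25,
                           overlap = 0.05, cfg = symbolic_config()) {
  stopifnot(inherits(sim, "sl_sim"))
  if (is.null(sync)) sync <- order_parameter(sim$phases, fs = sim$fs)
  n_units <- nrow(sim$phases)
  starts <- windowize(ncol(sim$phases), sim$fs, window, overlap)
  wlen <- attr(starts, "window_samples")
  cfg <- rescale_symbol_lag(cfg, sim$fs)
  span <- (cfg$m - 1L) * cfg$tau_sym
  if (wlen <= span)
    stop("window shorter than one full ordinal pattern span")
  # symbols from the real part of z (the simulated signal); window w covers
  # symbol positions starts[w] .. starts[w] + wlen - span - 1
  sym <- symbolize_cpp(Re(sim$z), cfg$m, cfg$tau_sym)
  smi_w <- window_mean_smi_cpp(sym, starts - 1L, wlen - span, cfg$m)
  samp_t <- inst_spearman_cpp(sim$amplitudes, rank(degrees))
  R <- chi <- samp <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + wlen - 1L)
    rw <- sync$r[idx]
    R[w] <- mean(rw)
    chi[w] <- susceptibility(rw, n_units)
    samp[w] <- mean(samp_t[idx])
  }
  data.frame(window_start = starts, R = R, chi = chi, smi = smi_w,
             s_amp = samp)
}
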