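# Surrogate multichannel signals. The EEG-stage analyses only assume
# band-limited oscillations whose global synchronization fluctuates in a
# controllable way, so the generator mixes a shared band-limited source into
# independent band-limited sources with a time-varying weight, rather than
# re-simulating oscillators at sensor level.

#' Generate surrogate EEG-like multichannel signals
#'
#' Each channel is `w(t) * common + (1 - w(t)) * independent + noise`,
#' band-pass filtered to `band`, where the mixing weight `w(t)` follows
#' `sync_profile` (interpolated over the recording). The realized windowed
#' order parameter is monotonically related to the profile: a profile of 1
#' gives near-identical channels (R close to 1), a profile of 0 gives
#' independent channels (R at the N-channel incoherence floor).
#'
#' @param n_channels number of channels.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (>= 250).
#' @param sync_profile numeric vector of target coherence in `[0, 1]`,
#'   linearly interpolated to the sample grid.
#' @param band length-2 pass band in Hz (default `c(4, 12)`).
#' @param seed integer seed.
#' @param noise_sd standard deviation of the additive sensor noise before the
#'   final band-pass, relative to unit-variance sources.
#' @return object of class `surrogate_eeg`: list with `signals`
#'   (channels x samples), `fs`, `band`, `w` (realized per-sample mixing
#'   weight), and `seed`.
#' @export
generate_surrogate_eeg <- function(n_channels, duration, fs, sync_profile,
                                   band = c(4, 12), seed, noise_sd = 0.05) {
  n_channels <- check_count(n_channels, "n_channels", min = 2L)
  stopifnot(duration > 0, fs >= 250)
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie within (0, fs/2)")
  stopifnot(all(sync_profile >= 0), all(sync_profile <= 1))
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)

  n <- round(duration * fs)
  w <- if (length(sync_profile) == 1L) rep(sync_profile, n) else
    approx(seq(0, 1, length.out = length(sync_profile)),
           sync_profile, xout = seq(0, 1, length.out = n))$y

  narrowband <- function() {
    v <- band_pass(rnorm(n), fs, band)
    v / sd(v)
  }
  common <- narrowband()
  x <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels))
    x[ch, ] <- w * common + (1 - w) * narrowband() + noise_sd * rnorm(n)
  x <- band_pass(x, fs, band)
  structure(list(signals = x, fs = fs, band = band, w = w, seed = seed),
            class = "surrogate_eeg")
}

#' Default co-activation templates with disjoint support
#'
#' Builds `k` parcel-space templates with (near-)disjoint support blocks and
#' mixed signs inside each block, so that both the signed (low-sync) and
#' rectified (high-sync) renderings of a template stay attributable to it.
#'
#' @param k number of templates.
#' @param n_parcels number of parcels (>= 2 * k).
#' @param amplitude magnitude of active entries.
#' @param seed integer seed.
#' @return k x n_parcels numeric matrix.
#' @export
cap_templates <- function(k, n_parcels, amplitude = 1, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  n_parcels <- check_count(n_parcels, "n_parcels", min = 2L * k)
  set.seed(check_count(seed, "seed", min = 0L))
  tmpl <- matrix(0, k, n_parcels)
  block <- floor(n_parcels / k)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * block + 1L):(j * block)
    signs <- sample(c(-1, 1), length(idx), replace = TRUE)
    if (all(signs > 0)) signs[1L] <- -1  # guarantee mixed sign
    if (all(signs < 0)) signs[1L] <- 1
    tmpl[j, idx] <- amplitude * signs
  }
  tmpl
}

#' Generate parcel BOLD volumes with planted co-activation structure
#'
#' Produces a volumes-by-parcels matrix in which every volume is one
#' template plus an oscillatory synchronization component plus Gaussian
#' noise. Volumes alternate (in blocks of `block_len`) between a low- and a
#' high-synchronization class: during high-class blocks all parcels share a
#' spatially uniform common oscillation (co-activation, one sign across
#' space at any instant), while during low-class blocks each parcel carries
#' an independent oscillation with its own phase (mixed sign across space),
#' so that the volume-wise synchronization measure ([volume_sync()])
#' separates the classes. Template identity per volume is drawn from the
#' class's occupancy distribution and persists for short runs so that
#' volume-to-volume dynamics stay smooth.
#'
#' @param n_parcels number of parcels.
#' @param n_volumes number of volumes (> k).
#' @param templates k x n_parcels matrix; default [cap_templates()] with
#'   `k = ncol(occupancy_by_class)`, or 3 templates if both are `NULL`.
#' @param occupancy_by_class 2 x k matrix of per-template rates, rows `low`
#'   and `high`, each row summing to 1; default uniform.
#' @param noise_sd Gaussian noise standard deviation.
#' @param sync_strength amplitude of the oscillatory synchronization
#'   component relative to unit template magnitude; 0 disables it (every
#'   volume then equals its template plus noise exactly).
#' @param period oscillation period in volumes.
#' @param block_len number of consecutive volumes sharing a class.
#' @param label_run maximal number of consecutive volumes sharing a
#'   template.
#' @param seed integer seed.
#' @return object of class `parcel_bold`: list with `volumes`
#'   (n_volumes x n_parcels), `template_labels`, `class_labels`
#'   (`"low"`/`"high"`), `templates`, and `seed`.
#' @export
generate_parcel_bold <- function(n_parcels, n_volumes, templates = NULL,
                                 occupancy_by_class = NULL, noise_sd = 0.2,
                                 sync_strength = 0.5, period = 10L,
                                 block_len = 10L, label_run = 5L, seed) {
  n_parcels <- check_count(n_parcels, "n_parcels", min = 2L)
  n_volumes <- check_count(n_volumes, "n_volumes", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(templates)) {
    k <- if (is.null(occupancy_by_class)) 3L else ncol(occupancy_by_class)
    templates <- cap_templates(k, n_parcels, seed = seed + 1L)
  }
  k <- nrow(templates)
  if (k > n_volumes) stop("more templates than volumes")
  if (ncol(templates) != n_parcels)
    stop("templates must have n_parcels columns")
  if (is.null(occupancy_by_class))
    occupancy_by_class <- matrix(1 / k, 2L, k)
  stopifnot(nrow(occupancy_by_class) == 2L, ncol(occupancy_by_class) == k)
  if (any(abs(rowSums(occupancy_by_class) - 1) > 1e-8))
    stop("each row of occupancy_by_class must sum to 1")
  rownames(occupancy_by_class) <- c("low", "high")

  set.seed(seed)
  cls <- rep(rep(c("low", "high"), each = block_len),
             length.out = n_volumes)
  lab <- integer(n_volumes)
  v <- 1L
  while (v <= n_volumes) {
    cl <- cls[v]
    l <- sample.int(k, 1L, prob = occupancy_by_class[cl, ])
    run <- min(label_run, n_volumes - v + 1L)
    run <- min(run, max(which(cls[v:(v + run - 1L)] == cl)))  # stay in class
    lab[v:(v + run - 1L)] <- l
    v <- v + run
  }
  tt <- seq_len(n_volumes)
  g <- sin(2 * pi * tt / period)                 # common, spatially uniform
  phi <- runif(n_parcels, 0, 2 * pi)             # per-parcel phase offsets
  w <- as.numeric(cls == "high")
  vol <- matrix(0, n_volumes, n_parcels)
  for (p in seq_len(n_parcels)) {
    b <- sin(2 * pi * tt / period + phi[p])      # independent, mixed sign
    vol[, p] <- templates[lab, p] +
      sync_strength * (w * g + (1 - w) * b) +
      noise_sd * rnorm(n_volumes)
  }
  structure(list(volumes = vol, template_labels = lab, class_labels = cls,
                 templates = templates, seed = seed),
            class = "parcel_bold")
}

#' Write / read a signal matrix with a JSON sidecar
#'
#' Stores a channels-by-samples matrix as a binary double array with a JSON
#' sidecar (`<path>.json`) holding dimensions, sampling rate, channel names,
#' and seed, for exchange between pipeline stages.
#'
#' @param x numeric matrix, channels x samples.
#' @param path output file path (binary payload).
#' @param fs sampling rate in Hz.
#' @param channels optional channel names.
#' @param seed optional integer recorded in the sidecar.
#' @return `write_signals` the path invisibly; `read_signals` a list with
#'   `signals`, `fs`, `channels`, `seed`.
#' @export
write_signals <- function(x, path, fs, channels = NULL, seed = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(x)), con, size = 8L)
  meta <- list(n_channels = nrow(x), n_samples = ncol(x), fs = fs,
               channels = channels %||% sprintf("ch%03d", seq_len(nrow(x))),
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples, size = 8L)
  list(signals = matrix(v, meta$n_channels, meta$n_samples, byrow = TRUE),
       fs = meta$fs, channels = meta$channels, seed = meta$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
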