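# Small fixtures built in code: hand-made connectomes/frequency sets for
# integrator tests, and a windowed order-parameter helper used across files.

make_connectome <- function(adjacency, distances) {
  structure(list(n_nodes = nrow(adjacency), adjacency = adjacency,
                 distances = distances,
                 labels = sprintf("node%03d", seq_len(nrow(adjacency))),
                 hubs = NULL, coords = NULL),
            class = "connectome")
}

make_freqs <- function(hz) {
  structure(list(omega = 2 * pi * hz, hz = hz, seed = NA_integer_),
            class = "frequency_set")
}

# fully connected connectome with uniform distances (mm)
full_connectome <- function(n, dist_mm = 70) {
  a <- matrix(1L, n, n); diag(a) <- 0L
  d <- matrix(dist_mm, n, n); diag(d) <- 0
  make_connectome(a, d)
}

# mean order parameter per window for a channels x samples real signal
windowed_R <- function(signals, fs, window = 0.25, overlap = 0.05) {
  sync <- order_parameter(Arg(analytic_signal(signals)), fs = fs)
  st <- windowize(ncol(signals), fs, window, overlap)
  len <- attr(st, "window_samples")
  vapply(st, function(s) mean(sync$r[s:(s + len - 1L)]), numeric(1))
}

# independent count-based SMI oracle: brute-force double sum over the
# m! x m! joint table (kept free of the package's C++ path)
smi_oracle <- function(xs, ys, m) {
  M <- factorial(m)
  tab <- matrix(0, M, M)
  for (t in seq_along(xs))
    tab[xs[t] + 1L, ys[t] + 1L] <- tab[xs[t] + 1L, ys[t] + 1L] + 1
  N <- length(xs)
  px <- rowSums(tab)
  py <- colSums(tab)
  mi <- 0
  for (a in seq_len(M)) for (b in seq_len(M)) {
    cc <- tab[a, b]
    if (cc > 0) mi <- mi + (cc / N) * log(cc * N / (px[a] * py[b]))
  }
  mi / log(M)
}

# map k-means cluster ids to planted template ids by contingency majority
align_labels <- function(cluster, truth) {
  tab <- table(cluster, truth)
  map <- apply(tab, 1L, which.max)
  as.integer(map[cluster])
}
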