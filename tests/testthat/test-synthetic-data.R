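# Synthetic generators: connectome invariants, natural-frequency law,
# surrogate EEG synchronization control, and planted parcel BOLD structure.

test_that("generated connectomes satisfy the structural invariants", {
  conn <- generate_connectome(78, 0.15, 0.15, seed = 1)
  expect_true(validate_connectome(conn))
  deg <- rowSums(conn$adjacency)
  expect_true(max(deg) >= 2 * median(deg))
  expect_true(all(deg[conn$hubs] >= 2 * median(deg)))

  dense <- generate_connectome(10, 0.9, 0.1, seed = 0)
  expect_true(isSymmetric(dense$adjacency))
  expect_true(all(diag(dense$adjacency) == 0))
  expect_true(all(dense$adjacency %in% c(0L, 1L)))

  # determinism under a fixed seed
  again <- generate_connectome(78, 0.15, 0.15, seed = 1)
  expect_identical(conn$adjacency, again$adjacency)
  expect_identical(conn$distances, again$distances)
  expect_error(generate_connectome(5, 0.15, 0.15, seed = 1), "n_nodes")
})

test_that("connectome plain-text round trip preserves the matrices", {
  conn <- generate_connectome(20, 0.2, 0.2, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_connectome(conn, prefix)
  back <- read_connectome(prefix)
  expect_identical(back$adjacency, conn$adjacency)
  expect_equal(back$distances, conn$distances, tolerance = 1e-12)
  expect_identical(back$labels, conn$labels)
})

test_that("natural frequencies follow the stated normal law in Hz", {
  f <- generate_frequencies(78, 10, 0.5, seed = 7)
  expect_lt(abs(mean(f$hz) - 10), 0.2)
  big <- generate_frequencies(1000, 10, 0.5, seed = 7)
  expect_lt(abs(sd(big$hz) - 0.5), 0.05)
  expect_true(all(big$omega > 0))
  expect_equal(big$omega, 2 * pi * big$hz)
  zero_var <- generate_frequencies(5, 10, 0, seed = 0)
  expect_equal(zero_var$omega, rep(2 * pi * 10, 5))
})

test_that("surrogate EEG synchronization tracks the requested profile", {
  e1 <- generate_surrogate_eeg(16, 10, 500, sync_profile = 1, seed = 2)
  R1 <- windowed_R(e1$signals, 500)
  expect_true(all(R1 > 0.9))

  # incoherent limit: mean windowed R below the N-channel floor
  # E[r] ~ sqrt(pi)/(2 sqrt(N)) for uniform independent phases
  e0 <- generate_surrogate_eeg(64, 20, 500, sync_profile = 0, seed = 2)
  R0 <- windowed_R(e0$signals, 500)
  bound <- sqrt(pi) / (2 * sqrt(64)) + 3 * sd(R0) / sqrt(length(R0))
  expect_lt(mean(R0), bound)

  # monotone in the constant profile level
  Rm <- windowed_R(generate_surrogate_eeg(16, 10, 500, 0.5, seed = 2)$signals,
                   500)
  Rl <- windowed_R(generate_surrogate_eeg(16, 10, 500, 0.0, seed = 2)$signals,
                   500)
  expect_lt(mean(Rl), mean(Rm))
  expect_lt(mean(Rm), mean(R1))

  # alternating profile: realized weight and windowed R strongly rank-linked
  ea <- generate_surrogate_eeg(16, 20, 500, rep(c(0, 1), 10), seed = 2)
  Ra <- windowed_R(ea$signals, 500)
  st <- windowize(ncol(ea$signals), 500)
  len <- attr(st, "window_samples")
  wa <- vapply(st, function(s) mean(ea$w[s:(s + len - 1L)]), numeric(1))
  expect_gt(cor(wa, Ra, method = "spearman"), 0.8)

  expect_error(generate_surrogate_eeg(16, 10, 500, 1, band = c(4, 300),
                                      seed = 1), "band")
})

test_that("parcel BOLD plants templates, classes, and occupancies", {
  # noiseless, no synchronization component: volumes equal their template
  clean <- generate_parcel_bold(30, 60, noise_sd = 0, sync_strength = 0,
                                seed = 4)
  for (v in seq_len(60))
    expect_equal(clean$volumes[v, ],
                 clean$templates[clean$template_labels[v], ])

  pb <- generate_parcel_bold(90, 600, noise_sd = 0.2, seed = 5)
  expect_identical(dim(pb$volumes), c(600L, 90L))
  expect_setequal(unique(pb$class_labels), c("low", "high"))
  # planted occupancy recovered within binomial sampling error (uniform 1/3)
  for (cl in c("low", "high")) {
    rates <- tabulate(pb$template_labels[pb$class_labels == cl], 3) /
      sum(pb$class_labels == cl)
    expect_true(all(abs(rates - 1 / 3) < 4 * sqrt((1 / 3) * (2 / 3) / 60)))
  }
  # determinism
  again <- generate_parcel_bold(90, 600, noise_sd = 0.2, seed = 5)
  expect_identical(pb$volumes, again$volumes)
  expect_error(generate_parcel_bold(10, 2, templates = cap_templates(4, 10),
                                    seed = 1), "templates than volumes")
})

test_that("signal matrix binary round trip with sidecar is lossless", {
  x <- matrix(rnorm(5 * 100), 5, 100)
  path <- file.path(withr::local_tempdir(), "sig.bin")
  write_signals(x, path, fs = 500, seed = 9L)
  back <- read_signals(path)
  expect_equal(back$signals, x, tolerance = 0)
  expect_equal(back$fs, 500)
  expect_equal(back$seed, 9L)
})
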