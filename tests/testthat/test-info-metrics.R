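# Ordinal symbolization and symbolic mutual information: rank-pattern
# arithmetic, the brute-force count oracle, rank-order invariances, and the
# phase-randomized surrogate filter.

test_that("symbolization maps rank orders to the m! ordinal alphabet", {
  cfg <- symbolic_config(m = 3, tau_sym = 1)
  # strictly increasing signal: one repeated ascending pattern
  up <- symbolize(seq(1, 10), cfg)
  expect_length(unique(up), 1L)
  # m = 3: alphabet of exactly 6 patterns, all realized on rich input
  set.seed(1)
  sym <- symbolize(rnorm(5000), cfg)
  expect_identical(sort(unique(sym)), 0:5)
  # pattern identity depends only on the rank order
  expect_identical(symbolize(c(3, 1, 2), cfg), symbolize(c(30, -5, 7), cfg))
  expect_false(symbolize(c(3, 1, 2), cfg) == symbolize(c(1, 2, 3), cfg))
  expect_false(symbolize(c(3, 1, 2), cfg) == symbolize(c(3, 2, 1), cfg))
  expect_error(symbolize(c(1, 2), cfg), "shorter")
})

test_that("SMI equals the brute-force count-based double sum", {
  cfg <- symbolic_config(m = 3, tau_sym = 2)
  set.seed(7)
  for (i in 1:50) {
    xs <- symbolize(rnorm(40), cfg)
    ys <- symbolize(rnorm(40), cfg)
    expect_equal(smi(xs, ys), smi_oracle(xs, ys, 3), tolerance = 1e-12)
  }
  # identical sequences with a uniform symbol distribution: SMI = 1
  xs <- rep(0:5, 20)
  expect_equal(smi(xs, xs), 1, tolerance = 1e-12)
  # independence: plug-in SMI small at length 1e4
  set.seed(8)
  a <- symbolize(rnorm(10000 + 2 * 14), symbolic_config())
  b <- symbolize(rnorm(10000 + 2 * 14), symbolic_config())
  expect_lt(smi(a, b), 0.05)
  expect_error(smi(0:5, 0:4), "length")
})

test_that("SMI is symmetric, rank-invariant, and bounded by entropy", {
  cfg <- symbolic_config(m = 3, tau_sym = 1)
  set.seed(9)
  x <- rnorm(300)
  y <- rnorm(300)
  xs <- symbolize(x, cfg)
  ys <- symbolize(y, cfg)
  expect_equal(smi(xs, ys), smi(ys, xs), tolerance = 1e-12)
  # strictly monotone transforms of the raw signal leave symbols unchanged
  expect_identical(symbolize(exp(x), cfg), xs)
  expect_identical(symbolize(-1 / (x - min(x) + 1), cfg), xs)
  # smi(x, x) = H(symbols)/log(6) <= 1
  ent <- {
    p <- tabulate(xs + 1L, 6) / length(xs)
    p <- p[p > 0]
    -sum(p * log(p)) / log(6)
  }
  expect_equal(smi(xs, xs), ent, tolerance = 1e-12)
  expect_lte(smi(xs, xs), 1)
})

test_that("phase randomization preserves each amplitude spectrum", {
  set.seed(10)
  x <- matrix(rnorm(4 * 1024), 4, 1024)
  set.seed(11)
  s <- phase_randomize(x)
  for (ch in 1:4)
    expect_equal(Mod(fft(s[ch, ])), Mod(fft(x[ch, ])), tolerance = 1e-8)
  expect_gt(max(abs(s - x)), 0.1)  # but the waveform itself changed
})

test_that("the surrogate filter keeps coupled pairs and rejects noise", {
  set.seed(12)
  fs <- 500
  n <- 10 * fs
  cfg <- symbolic_config()
  # independent channels: retained fraction near the significance level
  noise <- matrix(rnorm(16 * n), 16, n)
  noise <- band_pass(noise, fs, c(4, 12))
  st <- windowize(n, fs)
  res <- pairwise_smi(noise, st, cfg, surrogate_filter = TRUE)
  expect_lt(res$retained_fraction, 0.06)
  # a strongly shared source keeps pairs and yields finite window SMI
  common <- band_pass(rnorm(n), fs, c(4, 12))
  coupled <- rbind(matrix(rep(common, 4), 4, byrow = TRUE) +
                     0.1 * matrix(rnorm(4 * n), 4, n),
                   matrix(rnorm(2 * n), 2, n))
  coupled <- band_pass(coupled, fs, c(4, 12))
  res2 <- pairwise_smi(coupled, st, cfg, surrogate_filter = TRUE)
  expect_true(all(res2$significant_mask[1:4, 1:4][upper.tri(diag(4))]))
  expect_true(all(is.finite(res2$mean_smi)))
  # identical channels: SMI equals the pattern entropy, near 1 for iid
  # continuous input (all 6 patterns equally likely)
  set.seed(13)
  x <- rnorm(900)
  two <- rbind(x, x)
  st2 <- windowize(900, 500)
  res3 <- pairwise_smi(two, st2, cfg = symbolic_config(tau_sym = 1))
  expect_true(all(res3$mean_smi > 0.9))
})
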