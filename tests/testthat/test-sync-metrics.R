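# Order parameter, PCF, susceptibility, windowing, classification, and the
# SMI-chi joint histogram: closed-form cases and invariances.

test_that("order parameter reproduces closed-form phase configurations", {
  # identical phases -> full coherence
  ph <- matrix(1.3, 5, 4)
  expect_equal(order_parameter(ph)$r, rep(1, 4))
  # symmetric cancellation
  ph4 <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 4, 3)
  expect_equal(order_parameter(ph4)$r, rep(0, 3), tolerance = 1e-12)
  # N = 2 at separation pi/3: r = cos(pi/6)
  ph2 <- matrix(c(0, pi / 3), 2, 1)
  expect_equal(order_parameter(ph2)$r, cos(pi / 6), tolerance = 1e-12)
  expect_error(order_parameter(matrix(0, 1, 10)), "2 units")
  # bounds and coherence-iff-equal on random inputs
  set.seed(1)
  for (i in 1:20) {
    ph <- matrix(runif(8 * 50, -pi, pi), 8, 50)
    r <- order_parameter(ph)$r
    expect_true(all(r >= 0 & r <= 1 + 1e-12))
  }
})

test_that("PCF and susceptibility match two-point closed forms", {
  expect_equal(pcf(rep(0.4, 10), n_units = 7), 0)
  expect_equal(pcf(rep(c(0.4, 0.6), 50), n_units = 10), 0.1,
               tolerance = 1e-12)
  expect_equal(susceptibility(rep(0.5, 8), 10), 0)
  expect_equal(susceptibility(c(0.4, 0.6), 10), 0.2, tolerance = 1e-12)
  expect_true(is.na(susceptibility(c(0, 0), 10)))
})

test_that("PCF and chi are invariant under a global phase shift", {
  set.seed(2)
  ph <- matrix(runif(10 * 200, -pi, pi), 10, 200)
  shifted <- ph + 1.234
  s1 <- order_parameter(ph)
  s2 <- order_parameter(shifted)
  expect_equal(s1$r, s2$r, tolerance = 1e-12)
  expect_equal(pcf(s1), pcf(s2), tolerance = 1e-12)
  expect_equal(susceptibility(s1$r, 10), susceptibility(s2$r, 10),
               tolerance = 1e-12)
})

test_that("windowize tiles the series with the configured stride", {
  st <- windowize(500, 500, window = 0.25, overlap = 0.05)
  expect_identical(as.integer(st), c(1L, 101L, 201L, 301L))
  expect_identical(attr(st, "window_samples"), 125L)
  expect_identical(attr(st, "stride_samples"), 100L)
  # window equal to the series: exactly one window
  one <- windowize(1000, 500, window = 2, overlap = 0.5)
  expect_identical(as.integer(one), 1L)
  # zero overlap: disjoint tiling
  dj <- windowize(1000, 500, window = 0.2, overlap = 0)
  expect_identical(diff(as.integer(dj)), rep(100L, length(dj) - 1L))
  # window longer than series: empty
  expect_length(windowize(100, 500, window = 0.25, overlap = 0.05), 0L)
})

test_that("window classification applies fixed and pooled thresholds", {
  cls <- classify_windows(c(0.2, 0.4, 0.6), "fixed")
  expect_identical(as.character(cls), c("low", "neither", "high"))
  # pooled: thresholds mean -/+ 0.5 sd
  cls2 <- classify_windows(c(0.39, 0.41, 0.61), "pooled",
                           pooled_stats = c(0.5, 0.2))
  expect_identical(as.character(cls2), c("low", "neither", "high"))
  expect_warning(cls3 <- classify_windows(rep(0.4, 5), "fixed"),
                 "eliminated")
  expect_true(all(cls3 == "neither"))
})

test_that("joint histogram bins anchored at zero conserve counts", {
  h <- joint_histogram(0.03, 0.15)
  expect_equal(sum(h$counts), 1)
  # the single count sits in SMI bin [0.02, 0.04) x chi bin [0.1, 0.2)
  expect_equal(h$counts[2, 2], 1)
  expect_equal(h$smi_edges[2:3], c(0.02, 0.04))
  expect_equal(h$chi_edges[2:3], c(0.1, 0.2))
  set.seed(3)
  s <- runif(500)
  x <- runif(500, 0, 3)
  expect_equal(sum(joint_histogram(s, x)$counts), 500)
  empty <- joint_histogram(numeric(0), numeric(0))
  expect_identical(dim(empty$counts), c(0L, 0L))
})

test_that("the symbolic transform resolves frequencies up to fs/(m tau)", {
  expect_equal(round(max_resolved_frequency(500, 3, 14), 1), 11.9)
  expect_equal(max_resolved_frequency(250, 3, 7), 250 / 21)
})
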