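# Integrator checks against closed-form limits of the Stuart-Landau normal
# form and convergence/determinism contracts.

test_that("uncoupled noiseless oscillators reach the Hopf limit radius", {
  conn <- generate_connectome(20, 0.2, 0.2, seed = 1)
  freqs <- generate_frequencies(20, seed = 1)
  for (lam in c(0.25, 1, 2.25)) {
    p <- sl_params(lam = lam, K = 0, beta = 0, t_saturate = 15,
                   t_analyze = 1)
    sim <- sl_simulate(conn, freqs, p, seed = 2)
    expect_true(all(abs(sim$amplitudes - sqrt(lam)) / sqrt(lam) < 0.01),
                label = sprintf("radius sqrt(%g) reached within 1%%", lam))
  }
  p <- sl_params(lam = -1, K = 0, beta = 0, t_saturate = 15, t_analyze = 1)
  sim <- sl_simulate(conn, freqs, p, seed = 2)
  expect_lt(max(sim$amplitudes), 1e-3)
})

test_that("two identical delay-free oscillators phase-lock under coupling", {
  conn <- full_connectome(2, dist_mm = 0)
  freqs <- make_freqs(c(10, 10))
  p <- sl_params(lam = 0.5, K = 1, alpha = 0, beta = 0, t_saturate = 10,
                 t_analyze = 5)
  sim <- sl_simulate(conn, freqs, p, seed = 1)
  r <- order_parameter(sim$phases)$r
  expect_gt(mean(r), 0.99)
  # independent check at a 10x finer step agrees
  p_fine <- sl_params(lam = 0.5, K = 1, alpha = 0, beta = 0,
                      t_saturate = 10, t_analyze = 5, dt = 1e-4)
  sim_fine <- sl_simulate(conn, freqs, p_fine, seed = 1)
  expect_gt(mean(order_parameter(sim_fine$phases)$r), 0.99)
})

test_that("noiseless trajectories are reproducible and step-converged", {
  conn <- generate_connectome(20, 0.2, 0.2, seed = 4)
  freqs <- generate_frequencies(20, seed = 4)
  p <- sl_params(lam = 1, K = 0.8, beta = 0, t_saturate = 5, t_analyze = 10)
  a <- sl_simulate(conn, freqs, p, seed = 7)
  b <- sl_simulate(conn, freqs, p, seed = 7)
  expect_identical(a$z, b$z)  # bit-for-bit at fixed dt and seed

  half <- sl_params(lam = 1, K = 0.8, beta = 0, t_saturate = 5,
                    t_analyze = 10, dt = 5e-4)
  sim_half <- sl_simulate(conn, freqs, half, seed = 7)
  R1 <- mean(order_parameter(a$phases)$r)
  R2 <- mean(order_parameter(sim_half$phases)$r)
  expect_lt(abs(R1 - R2) / R1, 0.02)
})

test_that("amplitudes respect the coupling-dependent energy bound", {
  conn <- generate_connectome(20, 0.25, 0.2, seed = 5)
  freqs <- generate_frequencies(20, seed = 5)
  p <- sl_params(lam = 1, K = 0.5, t_saturate = 5, t_analyze = 10)
  sim <- sl_simulate(conn, freqs, p, seed = 6)
  bound <- sqrt(p$lam + p$K * max(rowSums(conn$adjacency))) + 0.5
  expect_lt(max(sim$amplitudes), bound)
})

test_that("sweep summaries are consistent with direct simulation", {
  conn <- generate_connectome(20, 0.2, 0.2, seed = 8)
  p <- sl_params(lam = 0.6, K = 0, t_saturate = 5, t_analyze = 10)
  sw <- sl_sweep(conn, 0.6, c(0.1, 0.6), n_seeds = 1, params_base = p,
                 seed = 11)
  expect_identical(nrow(sw$summary), 2L)
  # deterministic: rerunning the sweep reproduces every summary value
  sw2 <- sl_sweep(conn, 0.6, c(0.1, 0.6), n_seeds = 1, params_base = p,
                  seed = 11)
  expect_identical(sw$summary, sw2$summary)
  # synchronization grows with coupling
  expect_gt(sw$summary$mean_R[sw$summary$K == 0.6],
            sw$summary$mean_R[sw$summary$K == 0.1])
})

test_that("uncoupled pair correlation matches the independent-phase value", {
  # for N independent uniform phases, E[r^2] = 1/N and E[r]^2 = pi/(4N),
  # so PCF = N Var(r) = 1 - pi/4
  conn <- make_connectome(matrix(0L, 50, 50), matrix(0, 50, 50))
  freqs <- generate_frequencies(50, seed = 9)
  p <- sl_params(lam = 1, K = 0, beta = 0, t_saturate = 5, t_analyze = 60)
  sim <- sl_simulate(conn, freqs, p, seed = 9)
  expect_lt(abs(pcf(order_parameter(sim$phases)) - (1 - pi / 4)), 0.08)
})
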