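test_that("axes validate their invariants", {
  expect_error(time_axis(c(0.1, 0.2)), "start at exactly 0")
  expect_error(time_axis(c(0, 0.1, 0.15)), "uniformly spaced")
  expect_error(distance_grid(c(3, 2)), "strictly increasing")
  expect_error(distance_grid(c(0.5, 1, 1.5)), "within 1-8 nm")
  expect_silent(time_axis(seq(0, 2, by = 0.01)))
})

test_that("dipolar kernel is 1 at t = 0 and bounded", {
  K <- dipolar_kernel(time_axis(seq(0, 2, by = 0.05)),
                      distance_grid(seq(1.5, 5, by = 0.5)))
  expect_equal(K[1L, ], rep(1, ncol(K)))
  expect_true(all(K <= 1 + 1e-9 & K >= -0.5 - 1e-9))
  expect_error(dipolar_kernel(time_axis(c(0, 1))[0], distance_grid()),
               "empty|finite")
})

test_that("kernel matches the midpoint-quadrature oracle to 1e-8", {
  t <- time_axis(seq(0, 3, length.out = 50))
  r <- distance_grid(seq(1, 6, length.out = 50))
  K <- dipolar_kernel(t, r)
  Kq <- oracle_kernel_quad(as.numeric(t), as.numeric(r), n = 200000L)
  expect_lt(max(abs(K - Kq)), 1e-8)
})

test_that("kernel column oscillates at the perpendicular dipolar frequency", {
  # dominant frequency of K(t, r) - mean is 52.04 / r^3 MHz
  r <- 2.5
  dt <- 0.002
  t <- seq(0, 3, by = dt)
  K <- dipolar_kernel(time_axis(t), distance_grid(c(1, r)))[, 2L]
  sp <- Mod(stats::fft(K - mean(K)))[seq_len(length(t) %/% 2)]
  freq <- (which.max(sp[-1L])) / (length(t) * dt)
  expect_equal(freq, 52.04 / r^3, tolerance = 0.05)
})

test_that("simulated traces honour depth, background and seed contracts", {
  grid <- distance_grid()
  flat <- trace_model(0, 0, gaussian_distribution(grid, 2.5, 0.1))
  tr <- simulate_trace(flat, time_axis(seq(0, 2, by = 0.01)), 0, 1)
  expect_equal(tr$signal, rep(1, length(tr$signal)))

  tm <- trace_model(0.3, 0, gaussian_distribution(grid, 2.5, 0.02))
  tr <- simulate_trace(tm, time_axis(seq(0, 2, by = 0.008)), 0, 1)
  expect_equal(tr$signal[1L], 1, tolerance = 1e-9)
  expect_gte(min(tr$signal), 1 - 2 * 0.3)

  a <- simulate_trace(tm, time_axis(seq(0, 2, by = 0.008)), 0.01, 42)
  b <- simulate_trace(tm, time_axis(seq(0, 2, by = 0.008)), 0.01, 42)
  expect_identical(a$signal, b$signal)
  set.seed(123)
  rng_before <- .Random.seed
  simulate_trace(tm, time_axis(seq(0, 2, by = 0.008)), 0.01, 7)
  expect_identical(rng_before, .Random.seed)
})

test_that("noiseless modulation depth is recoverable from the trace tail", {
  grid <- distance_grid()
  t <- seq(0, 2, by = 0.008)
  for (mu in c(2.0, 2.8, 3.4)) {
    for (dep in c(0.1, 0.45)) {
      tm <- trace_model(dep, 0.05, gaussian_distribution(grid, mu, 0.12))
      tr <- simulate_trace(tm, time_axis(t), 0, 0)
      tail <- t >= 1.2
      dep_hat <- 1 - mean(tr$signal[tail] / exp(-0.05 * t[tail]))
      expect_lt(abs(dep_hat - dep), 0.01)
    }
  }
})

test_that("pair fraction counts bound spins with an in-dimer partner", {
  expect_equal(pair_fraction(occupancy_state(0, 0, 1)), 1)
  expect_equal(pair_fraction(occupancy_state(0.5, 0.5, 0)), 0)
  expect_equal(pair_fraction(occupancy_state(0.70, 0.21, 0.09)), 0.18 / 0.39)
  expect_error(pair_fraction(occupancy_state(1, 0, 0)), "undefined")
})

test_that("observables map occupancy to depth and bound-spin signal", {
  lab <- labeling_model(0.4, 1)
  obs <- observables_from_state(occupancy_state(0.70, 0.21, 0.09), lab)
  expect_equal(obs$bound_signal, 0.39)
  expect_equal(obs$depth, 0.4 * 0.18 / 0.39)

  empty <- observables_from_state(occupancy_state(1, 0, 0), lab)
  expect_equal(empty$depth, 0)
  expect_equal(empty$bound_signal, 0)

  dead <- observables_from_state(occupancy_state(0.5, 0.3, 0.2),
                                 labeling_model(0.4, 0))
  expect_equal(dead$depth, 0)
  expect_equal(dead$bound_signal, 0)
})
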