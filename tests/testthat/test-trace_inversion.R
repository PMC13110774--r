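test_that("background fit recovers rate and depth on pure exponentials", {
  t <- time_axis(seq(0, 2, by = 0.01))
  tr <- dipolar_trace(t, exp(-0.2 * as.numeric(t)))
  bg <- fit_background(tr)
  expect_equal(bg$background_rate_hat, 0.2, tolerance = 1e-6)
  expect_equal(bg$depth_hat, 0, tolerance = 1e-6)

  flat <- dipolar_trace(t, rep(1, length(t)))
  bgf <- fit_background(flat)
  expect_equal(bgf$background_rate_hat, 0, tolerance = 1e-9)
  expect_equal(bgf$depth_hat, 0, tolerance = 1e-9)

  short <- dipolar_trace(time_axis(seq(0, 0.05, by = 0.01)), rep(1, 6))
  expect_error(fit_background(short, 0.9), "fewer than 4")
  expect_error(fit_background(tr, 1.2), "fit_start_fraction")
})

test_that("background fit brackets the depth of a modulated trace", {
  tr <- make_gaussian_trace(2.5, 0.1, depth = 0.18, k = 0.05, snr = Inf)
  bg <- fit_background(tr)
  expect_gt(bg$depth_hat, 0.16)
  expect_lt(bg$depth_hat, 0.20)
})

test_that("noiseless single-point truth is recovered almost exactly", {
  grid <- distance_grid()
  r <- as.numeric(grid)
  d <- distance_distribution(grid, as.numeric(r == 3.0))
  tr <- simulate_trace(trace_model(0.3, 0, d), time_axis(seq(0, 2, by = 0.008)), 0, 0)
  inv <- invert_trace(tr, alpha = 1e-6)
  expect_equal(inv$modal_distance, 3.0)
  w <- r[2L] - r[1L]
  near <- abs(r - 3.0) <= w + 1e-9
  mass <- pracma::trapz(r[near], inv$distribution$density[near])
  expect_gte(mass + 2e-3, 0.99)  # trapezoid edge slack on a 3-point window
  expect_equal(inv$depth_hat, 0.3, tolerance = 1e-3)
})

test_that("recovered densities are non-negative and normalized", {
  for (s in 1:3) {
    tr <- make_gaussian_trace(2 + 0.5 * s, snr = 30, seed = s)
    inv <- invert_trace(tr)
    dens <- inv$distribution$density
    expect_true(all(dens >= 0))
    expect_equal(pracma::trapz(as.numeric(inv$distribution$grid), dens), 1,
                 tolerance = 1e-9)
  }
})

test_that("the in-vitro-like scenario yields a narrow peak at 2.5 nm", {
  tr <- make_gaussian_trace(2.5, 0.1, depth = 0.18, k = 0.05, snr = 50, seed = 1)
  inv <- invert_trace(tr)
  expect_equal(inv$modal_distance, 2.5, tolerance = 0.026)
})

test_that("bimodal truths produce two modes at the true positions", {
  grid <- distance_grid()
  mix <- compose_hypothesis("bi", list(
    list(distribution = gaussian_distribution(grid, 2.2, 0.12), weight = 0.5),
    list(distribution = gaussian_distribution(grid, 3.2, 0.12), weight = 0.5)
  ))
  tr <- simulate_trace(trace_model(0.3, 0.05, mix$predicted),
                       time_axis(seq(0, 2.5, by = 0.008)), 0.3 / 100, 11)
  inv <- invert_trace(tr)
  dens <- inv$distribution$density
  r <- as.numeric(grid)
  peaks <- which(diff(sign(diff(dens))) == -2) + 1L
  peaks <- peaks[dens[peaks] > 0.2 * max(dens)]
  expect_length(peaks, 2L)
  expect_equal(r[peaks], c(2.2, 3.2), tolerance = 0.026)
})

test_that("GCV picks little smoothing for clean data, more for noisy", {
  grid <- distance_grid()
  r <- as.numeric(grid)
  d <- distance_distribution(grid, as.numeric(r == 3.0))
  clean <- simulate_trace(trace_model(0.3, 0, d),
                          time_axis(seq(0, 2, by = 0.008)), 0, 0)
  expect_lte(select_alpha(clean, grid), 1e-2)
  expect_equal(select_alpha(clean, grid, alphas = 0.3), 0.3)
  expect_error(select_alpha(clean, grid, alphas = c(0.1, 0.2)), "at least 5")

  # alpha increases with noise: majority vote over seeds
  more <- vapply(1:10, function(s) {
    t5 <- make_gaussian_trace(2.5, snr = 5, seed = s)
    t100 <- make_gaussian_trace(2.5, snr = 100, seed = s)
    select_alpha(t5, grid) > select_alpha(t100, grid)
  }, logical(1))
  expect_gt(mean(more), 0.5)
})

test_that("modal distance uses the grid and breaks ties downward", {
  grid <- distance_grid(seq(2, 3, by = 0.1))
  expect_equal(modal_distance(
    distance_distribution(grid, c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0))), 2.2)
  uni <- distance_distribution(grid, rep(1, 11))
  expect_equal(modal_distance(uni), 2.0)
  g <- gaussian_distribution(distance_grid(), 4.1, 0.15)
  expect_equal(modal_distance(g), 4.1, tolerance = 0.026)
})

test_that("reliability limit follows the cube-root law", {
  expect_equal(reliability_limit(1.5), 4.0, tolerance = 1e-9)
  expect_equal(reliability_limit(0.8), 3.24, tolerance = 0.01)
  expect_equal(reliability_limit(8 * 1.5), 2 * reliability_limit(1.5))
  expect_error(reliability_limit(0), "positive")
})

test_that("truncated windows flag long distances as unreliable", {
  tr <- make_gaussian_trace(4.1, 0.15, t_max = 0.8, snr = 50, seed = 3)
  inv <- invert_trace(tr)
  expect_false(inv$reliable)
  ok <- make_gaussian_trace(2.5, 0.1, snr = 50, seed = 3)
  expect_true(invert_trace(ok)$reliable)
})

test_that("bootstrap band is degenerate without noise and reproducible", {
  tr0 <- make_gaussian_trace(2.5, 0.1, snr = Inf)
  b0 <- bootstrap_band(tr0, n_boot = 25L, seed = 1)
  expect_lt(max(b0$band_hi - b0$band_lo), 1e-3)

  tr <- make_gaussian_trace(2.5, 0.1, snr = 50, seed = 5)
  b1 <- bootstrap_band(tr, n_boot = 25L, seed = 9)
  b2 <- bootstrap_band(tr, n_boot = 25L, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_band(tr, n_boot = 5L), "n_boot")
})

test_that("bootstrap band covers the truth at most grid points", {
  grid <- distance_grid()
  truth <- gaussian_distribution(grid, 2.5, 0.1)
  sel <- truth$density > 1e-3
  cov <- vapply(1:10, function(s) {
    tr <- make_gaussian_trace(2.5, 0.1, snr = 50, seed = s)
    bb <- bootstrap_band(tr, n_boot = 40L, seed = s)
    mean(truth$density[sel] >= bb$band_lo[sel] &
         truth$density[sel] <= bb$band_hi[sel])
  }, numeric(1))
  expect_gte(mean(cov), 0.9)
})

test_that("inversion rejects degenerate inputs", {
  t <- time_axis(seq(0, 2, by = 0.1))
  expect_error(invert_trace(dipolar_trace(t, rep(0, length(t)))),
               "identically zero")
  expect_error(invert_trace(dipolar_trace(time_axis(seq(0, 0.9, by = 0.1)),
                                          rep(1, 10))), "at least 30")
})
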