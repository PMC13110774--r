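# Independent numerical oracles used to validate the package's own routes.

# Midpoint-rule quadrature of the orientation-averaged dipolar kernel,
# independent of the package's Gauss-Legendre implementation.
oracle_kernel_quad <- function(tvec, rvec, n = 10000L) {
  x <- (seq_len(n) - 0.5) / n
  K <- matrix(0, length(tvec), length(rvec))
  for (j in seq_along(rvec)) {
    om <- 2 * pi * 52.04 / rvec[j]^3
    K[, j] <- rowMeans(cos(outer(tvec * om, 3 * x^2 - 1)))
  }
  K
}

# Independent reference route for the modal distance of a DEER trace: a
# parametric time-domain fit of a single-Gaussian distance model
# (mu, sigma, depth, k) by Nelder-Mead, on a midpoint-quadrature kernel.
# Shares no code with the Tikhonov inversion path.
oracle_modal_gauss <- function(trace, mu_starts = seq(2, 5, by = 0.5)) {
  t <- as.numeric(trace$time)
  v <- trace$signal
  rg <- seq(1.2, 5.8, by = 0.02)
  Kq <- oracle_kernel_quad(t, rg, n = 400L)
  sse <- function(par) {
    mu <- par[1L]
    sg <- exp(par[2L])
    dep <- stats::plogis(par[3L])
    k <- exp(par[4L])
    w <- stats::dnorm(rg, mu, sg)
    sw <- sum(w)
    if (sw <= 0) return(1e10)
    f <- as.vector(Kq %*% (w / sw))
    sum((v - ((1 - dep) + dep * f) * exp(-k * t))^2)
  }
  best <- NULL
  for (mu0 in mu_starts) {
    o <- stats::optim(c(mu0, log(0.12), stats::qlogis(0.2), log(0.05)), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par[1L]
}

# Convenience: noisy trace from a single-Gaussian distance truth.
make_gaussian_trace <- function(mu, sigma = 0.1, depth = 0.18, k = 0.05,
                                t_max = 2, dt = 0.008, snr = 50, seed = 1,
                                grid = distance_grid()) {
  tm <- trace_model(depth, k, gaussian_distribution(grid, mu, sigma))
  noise_sd <- if (is.finite(snr)) depth / snr else 0
  simulate_trace(tm, time_axis(seq(0, t_max, by = dt)), noise_sd, seed)
}

random_occupancy_state <- function() {
  f <- stats::runif(3)
  f <- f / sum(f)
  occupancy_state(f[1L], f[2L], f[3L])
}
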