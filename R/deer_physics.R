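# Dipolar coupling constant for two free electrons, MHz * nm^3.
DIPOLAR_CONSTANT_MHZ_NM3 <- 52.04

#' Dipolar kernel matrix
#'
#' Orientation-averaged two-spin dipolar signal
#' \deqn{K(t, r) = \int_0^1 \cos[(3x^2 - 1)\,\omega(r)\,t]\,dx,\qquad
#'       \omega(r) = 2\pi D / r^3,}
#' with `D = 52.04` MHz nm^3 (free-electron g value). Isotropic averaging is
#' appropriate when orientation selection is negligible. Each column is
#' evaluated by composite 16-point Gauss--Legendre quadrature with the panel
#' count adapted to the dipolar phase, accurate to better than 1e-8.
#'
#' @param time A [time_axis()] (µs).
#' @param grid A [distance_grid()] (nm).
#' @param D Dipolar constant in MHz nm^3; default the free-electron value.
#' @return Matrix `[time, distance]`; `K(0, r) = 1` exactly, entries in
#'   `[-0.5, 1]`.
#' @export
dipolar_kernel <- function(time, grid, D = DIPOLAR_CONSTANT_MHZ_NM3) {
  time <- as.numeric(as_time_axis(time))
  grid <- as.numeric(as_distance_grid(grid))
  if (length(time) == 0L || length(grid) == 0L) {
    stop("empty axis", call. = FALSE)
  }
  gl <- pracma::gaussLegendre(16L, 0, 1)
  t_max <- max(time)
  K <- matrix(NA_real_, length(time), length(grid))
  for (j in seq_along(grid)) {
    omega <- 2 * pi * D / grid[j]^3
    # total phase excursion of the integrand is 3 * omega * t_max rad;
    # ~10 rad per 16-point panel keeps the panel error below 1e-12
    m <- max(2L, ceiling(3 * omega * t_max / 9))
    h <- 1 / m
    x <- as.vector(outer(gl$x * h, (seq_len(m) - 1L) * h, `+`))
    w <- rep(gl$w * h, m)
    K[, j] <- as.vector(cos(outer(time * omega, 3 * x^2 - 1)) %*% w)
  }
  K[time == 0, ] <- 1
  K
}

#' Labelling model: excitation efficiency and spin survival
#'
#' `inversion_efficiency` (lambda) is the probability that the pump pulse
#' flips the partner spin, which scales the modulation depth; `spin_survival`
#' (s) is the per-label probability that a nitroxide is still paramagnetic
#' at measurement time (below 1 in the reducing cytoplasm).
#'
#' @param inversion_efficiency Lambda in (0, 1]; default 0.4.
#' @param spin_survival s in \[0, 1\]; default 1 (in vitro).
#' @return A `labeling_model`.
#' @export
labeling_model <- function(inversion_efficiency = 0.4, spin_survival = 1) {
  if (!is.finite(inversion_efficiency) ||
      inversion_efficiency <= 0 || inversion_efficiency > 1) {
    stop("inversion_efficiency must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(spin_survival) || spin_survival < 0 || spin_survival > 1) {
    stop("spin_survival must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(inversion_efficiency = inversion_efficiency,
         spin_survival = spin_survival),
    class = "labeling_model"
  )
}

#' Parametric DEER trace model
#'
#' Noiseless model signal
#' \deqn{V(t) = [(1-\Delta) + \Delta \textstyle\sum_j K(t, r_j) p_j \Delta r]
#'       \exp(-k t^{d/3}),}
#' a two-spin form factor with modulation depth `depth` over a homogeneous
#' background of fractal dimension `background_dim` (3 = ordinary
#' exponential).
#'
#' @param depth Modulation depth Delta in \[0, 1\].
#' @param background_rate Background decay rate k >= 0 (1/µs).
#' @param distribution A [distance_distribution()].
#' @param background_dim Background dimensionality d > 0; default 3.
#' @return A `trace_model`.
#' @export
trace_model <- function(depth, background_rate, distribution,
                        background_dim = 3) {
  if (!is.finite(depth) || depth < 0 || depth > 1) {
    stop("depth must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(background_rate) || background_rate < 0) {
    stop("background_rate must be >= 0", call. = FALSE)
  }
  if (background_dim <= 0) stop("background_dim must be > 0", call. = FALSE)
  stopifnot(inherits(distribution, "distance_distribution"))
  structure(
    list(depth = depth, background_rate = background_rate,
         distribution = distribution, background_dim = background_dim),
    class = "trace_model"
  )
}

#' Dipolar trace container
#'
#' @param time A [time_axis()].
#' @param signal Amplitudes, normalized so the first point is 1 for
#'   noiseless synthetic traces.
#' @param noise_sd Known or estimated noise standard deviation (>= 0).
#' @return A `dipolar_trace` with elements `time`, `signal`, `noise_sd`.
#' @export
dipolar_trace <- function(time, signal, noise_sd = 0) {
  time <- as_time_axis(time)
  signal <- as.numeric(signal)
  if (length(signal) != length(time)) {
    stop("signal length must match time axis", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("signal must be finite", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(time = time, signal = signal, noise_sd = noise_sd),
            class = "dipolar_trace")
}

#' @export
print.dipolar_trace <- function(x, ...) {
  t <- as.numeric(x$time)
  cat(sprintf("<dipolar_trace> %d points, t_max %.3g µs, noise sd %.3g\n",
              length(t), max(t), x$noise_sd))
  invisible(x)
}

# trapezoid integration weights for a uniform grid
trapz_weights <- function(r) {
  n <- length(r)
  w <- rep(r[2L] - r[1L], n)
  w[c(1L, n)] <- w[1L] / 2
  w
}

model_signal <- function(model, time) {
  time <- as_time_axis(time)
  r <- as.numeric(model$distribution$grid)
  K <- dipolar_kernel(time, model$distribution$grid)
  ff <- as.vector(K %*% (model$distribution$density * trapz_weights(r)))
  bg <- exp(-model$background_rate * as.numeric(time)^(model$background_dim / 3))
  ((1 - model$depth) + model$depth * ff) * bg
}

#' Simulate a DEER trace
#'
#' Evaluates the model signal on the time axis and adds i.i.d. zero-mean
#' Gaussian noise. Identical seed and inputs give bitwise-identical output;
#' the global RNG state is left untouched.
#'
#' @param model A [trace_model()].
#' @param time A [time_axis()].
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A [dipolar_trace()] with `noise_sd` recorded.
#' @export
simulate_trace <- function(model, time, noise_sd = 0, seed = 0L) {
  stopifnot(inherits(model, "trace_model"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  time <- as_time_axis(time)
  v <- model_signal(model, time)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
    v <- v + noise
  }
  dipolar_trace(time, v, noise_sd)
}

#' Fraction of bound spins with an in-dimer partner
#'
#' For an occupancy state with fractions (f0, f1, f2) of dimers carrying 0,
#' 1 or 2 spin-labelled ligands, the probability that a randomly chosen
#' bound spin sits in a doubly-occupied dimer is
#' `q = 2 f2 / (f1 + 2 f2)`. This is the quantity the DEER modulation depth
#' counts.
#'
#' @param state An [occupancy_state()].
#' @return q in \[0, 1\].
#' @export
pair_fraction <- function(state) {
  state <- as_occupancy_state(state)
  denom <- state$f1 + 2 * state$f2
  if (denom <= 0) {
    stop("no bound spins: pair fraction is undefined", call. = FALSE)
  }
  2 * state$f2 / denom
}

#' Observables implied by an occupancy state
#'
#' Forward map from per-dimer occupancy to the two EPR observables:
#' modulation depth `depth = lambda * q` computed on the state after label
#' loss ([apply_spin_reduction()]), and the bound-spin signal
#' `bound_signal = f1' + 2 f2'`, the mean number of surviving bound spins
#' per dimer. Exact inverse of [infer_occupancy()] when `spin_survival = 1`.
#'
#' @param state An [occupancy_state()].
#' @param labels A [labeling_model()].
#' @return List with `depth` and `bound_signal`.
#' @export
observables_from_state <- function(state, labels = labeling_model()) {
  state <- as_occupancy_state(state)
  stopifnot(inherits(labels, "labeling_model"))
  surv <- apply_spin_reduction(state, labels$spin_survival)
  m <- surv$f1 + 2 * surv$f2
  if (m <= 0) {
    return(list(depth = 0, bound_signal = 0))
  }
  q <- pair_fraction(surv)
  list(depth = labels$inversion_efficiency * q, bound_signal = m)
}
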