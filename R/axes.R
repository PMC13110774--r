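#' Time axis for a dipolar evolution trace
#'
#' Constructs and validates the time axis of a DEER trace: times in
#' microseconds, starting at exactly zero, strictly increasing and uniformly
#' spaced.
#'
#' @param values Numeric vector of times in microseconds.
#' @return A `time_axis` object (numeric vector with class attribute).
#' @export
time_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("time axis must hold at least two finite values", call. = FALSE)
  }
  if (abs(values[1L]) > 1e-12) {
    stop("time axis must start at exactly 0 µs", call. = FALSE)
  }
  dt <- diff(values)
  if (any(dt <= 0)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-9) {
    stop("time axis must be uniformly spaced (within 1e-9 µs)", call. = FALSE)
  }
  structure(values, class = "time_axis")
}

#' Distance grid for distance distributions
#'
#' Uniform, strictly increasing grid of inter-spin distances in nanometres.
#' DEER is informative roughly between 1.5 and 8 nm; the grid is restricted
#' to 1--8 nm.
#'
#' @param values Numeric vector of distances in nm, or `NULL` for the default
#'   grid (1.0--6.0 nm in 0.025 nm steps).
#' @return A `distance_grid` object.
#' @export
distance_grid <- function(values = NULL) {
  if (is.null(values)) values <- seq(1, 6, by = 0.025)
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("distance grid must hold at least two finite values", call. = FALSE)
  }
  dr <- diff(values)
  if (any(dr <= 0)) stop("distance grid must be strictly increasing", call. = FALSE)
  if (max(dr) - min(dr) > 1e-9) {
    stop("distance grid must be uniformly spaced", call. = FALSE)
  }
  if (values[1L] < 1 - 1e-9 || values[length(values)] > 8 + 1e-9) {
    stop("distance grid must lie within 1-8 nm", call. = FALSE)
  }
  structure(values, class = "distance_grid")
}

#' Distance distribution P(r)
#'
#' Probability density over a distance grid, non-negative and normalized to
#' unit trapezoidal integral.
#'
#' @param grid A [distance_grid()].
#' @param density Non-negative densities (1/nm), one per grid point.
#' @param normalize Renormalize to unit integral (default `TRUE`).
#' @return A `distance_distribution` with elements `grid` and `density`.
#' @export
distance_distribution <- function(grid, density, normalize = TRUE) {
  grid <- as_distance_grid(grid)
  density <- as.numeric(density)
  if (length(density) != length(grid)) {
    stop("density length must match grid length", call. = FALSE)
  }
  if (anyNA(density) || any(!is.finite(density))) {
    stop("density must be finite", call. = FALSE)
  }
  if (any(density < -1e-12)) stop("density must be non-negative", call. = FALSE)
  density[density < 0] <- 0
  mass <- pracma::trapz(as.numeric(grid), density)
  if (normalize) {
    if (mass <= 0) stop("density has zero mass; cannot normalize", call. = FALSE)
    density <- density / mass
  } else if (abs(mass - 1) > 1e-6) {
    stop("density must integrate to 1 within 1e-6", call. = FALSE)
  }
  structure(list(grid = grid, density = density), class = "distance_distribution")
}

as_time_axis <- function(x) {
  if (inherits(x, "time_axis")) x else time_axis(x)
}

as_distance_grid <- function(x) {
  if (inherits(x, "distance_grid")) x else distance_grid(x)
}

#' @export
print.distance_distribution <- function(x, ...) {
  r <- as.numeric(x$grid)
  cat(sprintf(
    "<distance_distribution> %d points, %.3g-%.3g nm, mode %.3g nm\n",
    length(r), min(r), max(r), modal_distance(x)
  ))
  invisible(x)
}

#' Modal distance of a distribution
#'
#' Grid point of maximum density; ties are broken toward the smaller
#' distance.
#'
#' @param dist A [distance_distribution()].
#' @return Modal distance in nm.
#' @export
modal_distance <- function(dist) {
  stopifnot(inherits(dist, "distance_distribution"))
  as.numeric(dist$grid)[which.max(dist$density)]
}

#' Evaluate a Gaussian distance model on a grid
#'
#' Gaussian density truncated to the grid bounds and renormalized; the
#' parametric building block for site-pair distance models.
#'
#' @param grid A [distance_grid()].
#' @param mean,sd Gaussian mean and standard deviation in nm.
#' @return A [distance_distribution()].
#' @export
gaussian_distribution <- function(grid, mean, sd) {
  grid <- as_distance_grid(grid)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  d <- stats::dnorm(as.numeric(grid), mean, sd)
  if (max(d) <= 0) {
    stop("Gaussian has no mass on the grid", call. = FALSE)
  }
  distance_distribution(grid, d)
}
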