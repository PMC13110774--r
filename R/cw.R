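#' Continuous-wave EPR spectrum
#'
#' First-derivative CW spectrum on a uniform magnetic-field axis.
#'
#' @param field Strictly increasing, uniformly spaced field axis in mT.
#' @param amplitude Derivative amplitude per point.
#' @return A `cw_spectrum` with elements `field` and `amplitude`.
#' @export
cw_spectrum <- function(field, amplitude) {
  field <- as.numeric(field)
  amplitude <- as.numeric(amplitude)
  if (length(field) < 8L || length(field) != length(amplitude)) {
    stop("field and amplitude must be equal-length vectors (>= 8 points)",
         call. = FALSE)
  }
  db <- diff(field)
  if (any(db <= 0) || max(db) - min(db) > 1e-9) {
    stop("field axis must be strictly increasing and uniform", call. = FALSE)
  }
  if (any(!is.finite(amplitude))) stop("amplitude must be finite", call. = FALSE)
  structure(list(field = field, amplitude = amplitude), class = "cw_spectrum")
}

#' Default CW field axis
#'
#' @param from,to Field range in mT.
#' @param n Number of points.
#' @return Numeric field axis.
#' @export
default_field_axis <- function(from = 328, to = 343, n = 1024L) {
  seq(from, to, length.out = n)
}

# double integral (spin count) of a first-derivative spectrum
double_integral <- function(field, amplitude) {
  absorp <- pracma::cumtrapz(field, amplitude)
  pracma::trapz(field, as.vector(absorp))
}

#' Free (fast-motion) nitroxide template
#'
#' Three equal-integral Lorentzian absorption lines at `center - hyperfine`,
#' `center`, `center + hyperfine` (the 14N triplet of a rapidly tumbling
#' nitroxide), returned as the analytic first derivative and normalized to
#' unit absorption double integral. `linewidth` is the Lorentzian half-width
#' at half-maximum; the derivative peak-to-peak width of each line is
#' `2 * linewidth / sqrt(3)`.
#'
#' @param field Field axis (mT).
#' @param center Spectrum center (mT); default 335.5.
#' @param hyperfine Nitrogen hyperfine splitting (mT); default 1.6.
#' @param linewidth Lorentzian HWHM (mT); default 0.15.
#' @return A [cw_spectrum()].
#' @export
make_free_template <- function(field, center = 335.5, hyperfine = 1.6,
                               linewidth = 0.15) {
  field <- as.numeric(field)
  if (linewidth <= 0 || hyperfine <= 0) {
    stop("linewidth and hyperfine must be positive", call. = FALSE)
  }
  need <- hyperfine + 5 * linewidth
  if (min(field) > center - need || max(field) < center + need) {
    stop("field axis must cover center +/- (hyperfine + 5 linewidth)",
         call. = FALSE)
  }
  deriv <- rep(0, length(field))
  for (b0 in center + c(-hyperfine, 0, hyperfine)) {
    x <- field - b0
    # d/dB of (1/3) * (linewidth/pi) / (x^2 + linewidth^2)
    deriv <- deriv - (2 / 3) * linewidth * x / (pi * (x^2 + linewidth^2)^2)
  }
  deriv <- deriv / double_integral(field, deriv)
  cw_spectrum(field, deriv)
}

#' Bound (rigid-limit) nitroxide template
#'
#' Broad powder-like surrogate for a rigidly bound label: a uniform
#' distribution of line positions across `outer_splitting` convolved with a
#' Gaussian of sd `linewidth`, returned as the analytic first derivative
#' and normalized to unit double integral. Antisymmetric about `center`.
#'
#' @param field Field axis (mT).
#' @param center Spectrum center (mT); default 335.5.
#' @param outer_splitting Full extent S of the powder envelope (mT);
#'   default 7.0 (2 Azz of an immobilized nitroxide).
#' @param linewidth Gaussian convolution sd (mT); default 0.4.
#' @return A [cw_spectrum()].
#' @export
make_bound_template <- function(field, center = 335.5, outer_splitting = 7,
                                linewidth = 0.4) {
  field <- as.numeric(field)
  if (outer_splitting <= 0) stop("outer_splitting must be positive", call. = FALSE)
  if (linewidth <= 0) stop("linewidth must be positive", call. = FALSE)
  need <- outer_splitting / 2 + 5 * linewidth
  if (min(field) > center - need || max(field) < center + need) {
    stop("field axis must cover center +/- (outer_splitting/2 + 5 linewidth)",
         call. = FALSE)
  }
  # absorption = [Phi((B-c+S/2)/w) - Phi((B-c-S/2)/w)] / S; derivative below
  lo <- (field - center + outer_splitting / 2) / linewidth
  hi <- (field - center - outer_splitting / 2) / linewidth
  deriv <- (stats::dnorm(lo) - stats::dnorm(hi)) /
    (outer_splitting * linewidth)
  deriv <- deriv / double_integral(field, deriv)
  cw_spectrum(field, deriv)
}

#' Pair of unit-integral component templates
#'
#' @param free,bound [cw_spectrum()] templates on the same axis, each with
#'   unit absorption double integral (within 1e-6).
#' @return A `component_templates`.
#' @export
component_templates <- function(free, bound) {
  stopifnot(inherits(free, "cw_spectrum"), inherits(bound, "cw_spectrum"))
  if (length(free$field) != length(bound$field) ||
      max(abs(free$field - bound$field)) > 1e-9) {
    stop("templates must share one field axis", call. = FALSE)
  }
  for (sp in list(free, bound)) {
    if (abs(double_integral(sp$field, sp$amplitude) - 1) > 1e-6) {
      stop("each template must have unit double integral", call. = FALSE)
    }
  }
  structure(list(free = free, bound = bound), class = "component_templates")
}

#' Default free/bound template pair
#'
#' @param field Field axis; default [default_field_axis()].
#' @return A [component_templates()].
#' @export
default_templates <- function(field = default_field_axis()) {
  component_templates(make_free_template(field), make_bound_template(field))
}

#' Unmix a CW spectrum into free and bound components
#'
#' Non-negative least-squares weights of the two derivative templates.
#' Because each template carries a unit absorption double integral, the
#' weights are proportional to spin counts and
#' `free_fraction = w_free / (w_free + w_bound)` is the unbound-spin
#' fraction — this is the physically correct spin-count convention (sharp
#' lines would otherwise dominate by amplitude).
#'
#' @param spectrum A [cw_spectrum()] on the template axis.
#' @param templates A [component_templates()]; default [default_templates()]
#'   on the spectrum's axis.
#' @return List with `free_fraction`, `residual_norm`, and the raw weights
#'   `w_free`, `w_bound`.
#' @export
unmix <- function(spectrum, templates = NULL) {
  stopifnot(inherits(spectrum, "cw_spectrum"))
  if (is.null(templates)) templates <- default_templates(spectrum$field)
  stopifnot(inherits(templates, "component_templates"))
  if (length(spectrum$field) != length(templates$free$field) ||
      max(abs(spectrum$field - templates$free$field)) > 1e-9) {
    stop("spectrum must lie on the template field axis", call. = FALSE)
  }
  A <- cbind(templates$free$amplitude, templates$bound$amplitude)
  fit <- pracma::lsqnonneg(A, spectrum$amplitude)
  w <- fit$x
  if (sum(w) <= 0) {
    stop("degenerate fit: both component weights are zero", call. = FALSE)
  }
  list(free_fraction = w[1L] / sum(w),
       residual_norm = sqrt(sum((spectrum$amplitude - A %*% w)^2)),
       w_free = w[1L], w_bound = w[2L])
}

#' Simulate a two-component CW spectrum
#'
#' Mixes the templates with spin-count weights `free_fraction` and
#' `1 - free_fraction` and adds white noise with
#' `sd = max(|amplitude|) / snr`.
#'
#' @param free_fraction Unbound-spin fraction in \[0, 1\].
#' @param templates A [component_templates()]; default
#'   [default_templates()].
#' @param snr Peak-amplitude signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed.
#' @return A [cw_spectrum()].
#' @export
simulate_cw_spectrum <- function(free_fraction, templates = default_templates(),
                                 snr = Inf, seed = 0L) {
  if (!is.finite(free_fraction) || free_fraction < 0 || free_fraction > 1) {
    stop("free_fraction must be in [0, 1]", call. = FALSE)
  }
  amp <- free_fraction * templates$free$amplitude +
    (1 - free_fraction) * templates$bound$amplitude
  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive", call. = FALSE)
    sd <- max(abs(amp)) / snr
    amp <- amp + withr::with_seed(seed, stats::rnorm(length(amp), 0, sd))
  }
  cw_spectrum(templates$free$field, amp)
}
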