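#' Per-dimer occupancy state
#'
#' Fractions of dimers carrying 0, 1 or 2 spin-labelled ligands.
#'
#' @param f0,f1,f2 Fractions in \[0, 1\] summing to 1 (within 1e-9).
#' @return An `occupancy_state`.
#' @export
occupancy_state <- function(f0, f1, f2) {
  f <- c(f0, f1, f2)
  if (any(!is.finite(f))) stop("fractions must be finite", call. = FALSE)
  if (any(f < -1e-9) || any(f > 1 + 1e-9)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("fractions must sum to 1 within 1e-9", call. = FALSE)
  }
  f <- pmin(pmax(f, 0), 1)
  structure(list(f0 = f[1L], f1 = f[2L], f2 = f[3L]), class = "occupancy_state")
}

as_occupancy_state <- function(x) {
  if (inherits(x, "occupancy_state")) return(x)
  x <- unlist(x)
  if (length(x) != 3L) stop("occupancy state needs exactly (f0, f1, f2)", call. = FALSE)
  occupancy_state(x[[1L]], x[[2L]], x[[3L]])
}

#' @export
print.occupancy_state <- function(x, ...) {
  cat(sprintf("<occupancy_state> f0 = %.4g, f1 = %.4g, f2 = %.4g\n",
              x$f0, x$f1, x$f2))
  invisible(x)
}

#' Infer occupancy fractions from modulation depth and bound-spin signal
#'
#' Inverts the spin-counting model: `q = depth / lambda` is the fraction of
#' bound spins with an in-dimer partner, `bound_signal = f1 + 2 f2` the mean
#' bound spins per dimer, giving `f2 = q * bound_signal / 2`,
#' `f1 = bound_signal * (1 - q)`. Exact algebraic inverse of
#' [observables_from_state()] at `spin_survival = 1`; with partial survival
#' it returns the state of the *surviving* labels.
#'
#' Noise can push the measured depth slightly above lambda; `q` is then
#' clipped to 1 with a warning rather than an error.
#'
#' @param depth Measured modulation depth.
#' @param bound_signal Mean bound spins per dimer, in \[0, 2\].
#' @param labels A [labeling_model()]; only `inversion_efficiency` enters.
#' @return An [occupancy_state()].
#' @export
infer_occupancy <- function(depth, bound_signal, labels = labeling_model()) {
  stopifnot(inherits(labels, "labeling_model"))
  lam <- labels$inversion_efficiency
  if (!is.finite(depth) || depth < 0 || depth > lam + 1e-9) {
    stop("depth must lie in [0, lambda]", call. = FALSE)
  }
  if (!is.finite(bound_signal) || bound_signal < 0 || bound_signal > 2) {
    stop("bound_signal must lie in [0, 2]", call. = FALSE)
  }
  q <- depth / lam
  if (q > 1) {
    warning("depth exceeds lambda; pair fraction clipped to 1")
    q <- 1
  }
  f2 <- q * bound_signal / 2
  f1 <- bound_signal * (1 - q)
  f0 <- 1 - f1 - f2
  if (f0 < -1e-9) {
    stop("infeasible observables: implied f0 is negative", call. = FALSE)
  }
  occupancy_state(max(f0, 0), f1, f2)
}

#' Thin an occupancy state by independent label loss
#'
#' Each label survives independently with probability `s` (nitroxide
#' reduction in the cytoplasm); occupancy refers to surviving paramagnetic
#' labels: `f2' = f2 s^2`, `f1' = f1 s + 2 f2 s (1 - s)`.
#'
#' @param state An [occupancy_state()].
#' @param s Survival probability in \[0, 1\].
#' @return The thinned [occupancy_state()].
#' @export
apply_spin_reduction <- function(state, s) {
  state <- as_occupancy_state(state)
  if (!is.finite(s) || s < 0 || s > 1) stop("s must be in [0, 1]", call. = FALSE)
  f2 <- state$f2 * s^2
  f1 <- state$f1 * s + 2 * state$f2 * s * (1 - s)
  occupancy_state(1 - f1 - f2, f1, f2)
}

#' Random-binding (binomial) null state
#'
#' The occupancy state expected if ligands distributed independently over
#' the two sites per dimer at the same mean load: with per-site occupancy
#' `p = (f1 + 2 f2) / 2`, the null is `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param state An [occupancy_state()].
#' @return The binomial-null [occupancy_state()].
#' @export
random_binding_null <- function(state) {
  state <- as_occupancy_state(state)
  p <- (state$f1 + 2 * state$f2) / 2
  occupancy_state((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Test for cooperative double occupancy
#'
#' Compares the observed doubly-occupied fraction with the binomial
#' random-binding expectation at equal mean load. The sampling uncertainty
#' of the ratio is assessed by a multinomial parametric bootstrap of
#' `n_dimers` dimers; the verdict is "cooperative" when the lower 2.5%
#' bound exceeds 1, "anti-cooperative" when the upper bound is below 1,
#' otherwise "indistinguishable".
#'
#' @param state Observed [occupancy_state()].
#' @param n_dimers Number of dimers the state was estimated from (>= 100);
#'   governs CI width only.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `cooperativity_report` list: `observed_f2`,
#'   `expected_f2_random`, `ratio`, `ci_lo`, `ci_hi`, `verdict`.
#' @export
cooperativity_test <- function(state, n_dimers = 5000L, n_boot = 1000L,
                               seed = 0L) {
  state <- as_occupancy_state(state)
  if (n_dimers < 100L) stop("n_dimers must be >= 100", call. = FALSE)
  null <- random_binding_null(state)
  if (null$f2 <= 0) {
    if (state$f2 > 0) {
      # cannot happen for a valid state (f2 > 0 forces p > 0) but keep the
      # contract explicit
      return(structure(
        list(observed_f2 = state$f2, expected_f2_random = 0, ratio = Inf,
             ci_lo = Inf, ci_hi = Inf, verdict = "cooperative"),
        class = "cooperativity_report"
      ))
    }
    return(structure(
      list(observed_f2 = 0, expected_f2_random = 0, ratio = NA_real_,
           ci_lo = NA_real_, ci_hi = NA_real_, verdict = "indistinguishable"),
      class = "cooperativity_report"
    ))
  }
  ratio <- state$f2 / null$f2
  probs <- c(state$f0, state$f1, state$f2)
  counts <- withr::with_seed(seed, stats::rmultinom(n_boot, n_dimers, probs))
  f <- counts / n_dimers
  p_hat <- (f[2L, ] + 2 * f[3L, ]) / 2
  r_boot <- ifelse(p_hat > 0, f[3L, ] / p_hat^2, NA_real_)
  ci <- stats::quantile(r_boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  verdict <- if (ci[1L] > 1) "cooperative"
             else if (ci[2L] < 1) "anti-cooperative"
             else "indistinguishable"
  structure(
    list(observed_f2 = state$f2, expected_f2_random = null$f2, ratio = ratio,
         ci_lo = ci[1L], ci_hi = ci[2L], verdict = verdict),
    class = "cooperativity_report"
  )
}

#' @export
print.cooperativity_report <- function(x, ...) {
  cat(sprintf(
    "<cooperativity_report> f2 obs %.4g vs random %.4g, ratio %.3g [%.3g, %.3g]: %s\n",
    x$observed_f2, x$expected_f2_random, x$ratio, x$ci_lo, x$ci_hi, x$verdict
  ))
  invisible(x)
}
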