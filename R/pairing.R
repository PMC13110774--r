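PAIR_NAMES <- c("a1-b1", "a1-b2", "a1-a2", "a2-b2")

# aliases implied by the two-fold dimer symmetry
PAIR_ALIASES <- c(
  "a1-b1" = "a1-b1", "b1-a1" = "a1-b1",
  "a1-b2" = "a1-b2", "b2-a1" = "a1-b2", "b1-a2" = "a1-b2", "a2-b1" = "a1-b2",
  "a1-a2" = "a1-a2", "a2-a1" = "a1-a2", "b1-b2" = "a1-a2", "b2-b1" = "a1-a2",
  "a2-b2" = "a2-b2", "b2-a2" = "a2-b2"
)

#' Four-site dimer geometry
#'
#' Gaussian inter-label distance models for the four distinct site pairs of
#' a homodimer with catalytic sites a.1/b.1 and interface secondary sites
#' a.2/b.2. Two-fold symmetry makes b1-a2 equivalent to a1-b2 and b1-b2 to
#' a1-a2. Defaults: catalytic--catalytic (a1-b1) 4.1 nm, cross
#' catalytic--opposite-secondary (a1-b2) 2.5 nm, intra-monomer (a1-a2)
#' 3.0 nm, secondary--secondary (a2-b2) 2.5 nm (not constrained by data;
#' configuration value), all with sd 0.15 nm.
#'
#' @param mu Named means (nm) for `"a1-b1"`, `"a1-b2"`, `"a1-a2"`,
#'   `"a2-b2"`.
#' @param sigma Single sd (nm) or named per-pair sds.
#' @return A `site_geometry`.
#' @export
site_geometry <- function(mu = c("a1-b1" = 4.1, "a1-b2" = 2.5,
                                 "a1-a2" = 3.0, "a2-b2" = 2.5),
                          sigma = 0.15) {
  if (!all(PAIR_NAMES %in% names(mu))) {
    stop("mu must name all four pairs: ", paste(PAIR_NAMES, collapse = ", "),
         call. = FALSE)
  }
  mu <- mu[PAIR_NAMES]
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("pair means must be positive", call. = FALSE)
  }
  if (length(sigma) == 1L) sigma <- stats::setNames(rep(sigma, 4L), PAIR_NAMES)
  if (!all(PAIR_NAMES %in% names(sigma)) || any(sigma <= 0)) {
    stop("sigma must be a positive scalar or name all four pairs",
         call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma[PAIR_NAMES]), class = "site_geometry")
}

canonical_pair <- function(pair) {
  out <- PAIR_ALIASES[pair]
  if (anyNA(out)) {
    stop("unknown site pair: ", paste(pair[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Model distance distribution for one site pair
#'
#' Gaussian with the pair's mean and sd, truncated to the grid and
#' renormalized.
#'
#' @param geometry A [site_geometry()].
#' @param pair Pair name (symmetry aliases such as `"b1-a2"` accepted).
#' @param grid A [distance_grid()].
#' @return A [distance_distribution()].
#' @export
pair_distribution <- function(geometry, pair, grid = distance_grid()) {
  stopifnot(inherits(geometry, "site_geometry"))
  pair <- canonical_pair(pair)
  gaussian_distribution(grid, geometry$mu[[pair]], geometry$sigma[[pair]])
}

#' Distance distribution from a coordinate ensemble
#'
#' Per-frame Euclidean distances between the two label positions (nm),
#' accumulated on the grid with per-source residence weights and smoothed
#' with a Gaussian kernel.
#'
#' @param frames Data frame with columns `frame`, `source`, `ax`, `ay`,
#'   `az`, `bx`, `by`, `bz` (positions in nm), e.g. read from CSV.
#' @param weights Named non-negative per-source weights (normalized
#'   internally), or `NULL` for uniform source weighting.
#' @param grid A [distance_grid()].
#' @param smoothing Gaussian kernel bandwidth in nm; default 0.05.
#' @return A [distance_distribution()].
#' @export
empirical_pair_distribution <- function(frames, weights = NULL,
                                        grid = distance_grid(),
                                        smoothing = 0.05) {
  grid <- as_distance_grid(grid)
  need <- c("frame", "source", "ax", "ay", "az", "bx", "by", "bz")
  if (!is.data.frame(frames) || !all(need %in% names(frames))) {
    stop("frames must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(frames) < 1L) stop("at least one frame is required", call. = FALSE)
  coord_cols <- need[-(1:2)]
  for (cl in coord_cols) {
    v <- suppressWarnings(as.numeric(frames[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("malformed coordinate in column '%s' at row %d", cl, bad[1L]),
           call. = FALSE)
    }
    frames[[cl]] <- v
  }
  d <- sqrt((frames$ax - frames$bx)^2 + (frames$ay - frames$by)^2 +
            (frames$az - frames$bz)^2)
  src <- as.character(frames$source)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(unique(src))), unique(src))
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  weights <- weights / sum(weights)
  if (!all(src %in% names(weights))) {
    stop("weights must name every source in frames", call. = FALSE)
  }
  # frame weight = source weight split evenly over that source's frames
  n_per <- table(src)
  w_frame <- as.numeric(weights[src] / n_per[src])
  if (smoothing <= 0) stop("smoothing must be positive", call. = FALSE)
  r <- as.numeric(grid)
  dens <- vapply(r, function(ri) {
    sum(w_frame * stats::dnorm(ri, d, smoothing))
  }, numeric(1))
  if (max(dens) <= 0) {
    stop("ensemble distances have no mass on the grid", call. = FALSE)
  }
  distance_distribution(grid, dens)
}

#' Compose a pairing hypothesis from component distributions
#'
#' Weighted mixture of site-pair distance distributions — the superposition
#' expected when a population occupies several pairings.
#'
#' @param name Hypothesis name.
#' @param parts List of `list(distribution, weight)` pairs (weights >= 0,
#'   not all zero, shared grid).
#' @return A `pairing_hypothesis` with elements `name`, `components`
#'   (weights, normalized), `predicted` ([distance_distribution()]).
#' @export
compose_hypothesis <- function(name, parts) {
  if (length(parts) < 1L) stop("parts must be non-empty", call. = FALSE)
  w <- vapply(parts, function(p) p$weight, numeric(1))
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  w <- w / sum(w)
  dists <- lapply(parts, function(p) p$distribution)
  g <- dists[[1L]]$grid
  for (dd in dists) {
    stopifnot(inherits(dd, "distance_distribution"))
    if (length(dd$grid) != length(g) || max(abs(dd$grid - g)) > 1e-9) {
      stop("all components must share one grid", call. = FALSE)
    }
  }
  mix <- Reduce(`+`, Map(function(dd, wi) wi * dd$density, dists, w))
  structure(
    list(name = as.character(name), components = w,
         predicted = distance_distribution(g, mix)),
    class = "pairing_hypothesis"
  )
}

#' Default pairing hypotheses for the four-site dimer
#'
#' Three candidate explanations of a doubly-occupied dimer's DEER distance:
#' `cross` (catalytic site of one monomer + secondary site of the other,
#' the symmetric superposition of a1+b2 and b1+a2, which coincide),
#' `both-catalytic` (a1+b1), and `intra-monomer` (catalytic + same-monomer
#' secondary, a1+a2 / b1+b2). Simultaneous occupation of only the two
#' secondary sites is deliberately not a default (add via
#' [compose_hypothesis()]).
#'
#' @param geometry A [site_geometry()].
#' @param grid A [distance_grid()].
#' @return Named list of [compose_hypothesis()] objects.
#' @export
default_hypotheses <- function(geometry = site_geometry(),
                               grid = distance_grid()) {
  cross <- compose_hypothesis("cross", list(
    list(distribution = pair_distribution(geometry, "a1-b2", grid), weight = 0.5),
    list(distribution = pair_distribution(geometry, "b1-a2", grid), weight = 0.5)
  ))
  cat2 <- compose_hypothesis("both-catalytic", list(
    list(distribution = pair_distribution(geometry, "a1-b1", grid), weight = 1)
  ))
  intra <- compose_hypothesis("intra-monomer", list(
    list(distribution = pair_distribution(geometry, "a1-a2", grid), weight = 0.5),
    list(distribution = pair_distribution(geometry, "b1-b2", grid), weight = 0.5)
  ))
  stats::setNames(list(cross, cat2, intra),
                  c("cross", "both-catalytic", "intra-monomer"))
}

#' Overlap score between a recovered and a predicted distribution
#'
#' Overlap coefficient `integral of min(recovered, predicted) dr` computed
#' over the reliable window `r <= r_limit` only, with both curves
#' renormalized on that window. Symmetric and scale-invariant; 1 for
#' identical curves, 0 for disjoint support.
#'
#' @param recovered A [distance_distribution()].
#' @param hypothesis A `pairing_hypothesis` (or a
#'   [distance_distribution()]).
#' @param r_limit Upper distance bound of the comparison window (nm), e.g.
#'   [reliability_limit()] of the trace length.
#' @return Score in \[0, 1\].
#' @export
score_hypothesis <- function(recovered, hypothesis, r_limit) {
  stopifnot(inherits(recovered, "distance_distribution"))
  pred <- if (inherits(hypothesis, "pairing_hypothesis")) {
    hypothesis$predicted
  } else {
    hypothesis
  }
  stopifnot(inherits(pred, "distance_distribution"))
  g <- as.numeric(recovered$grid)
  if (length(pred$grid) != length(g) || max(abs(as.numeric(pred$grid) - g)) > 1e-9) {
    stop("distributions must share one grid", call. = FALSE)
  }
  keep <- g <= r_limit
  if (sum(keep) < 2L) stop("reliable window contains fewer than 2 grid points",
                           call. = FALSE)
  gw <- g[keep]
  a <- recovered$density[keep]
  b <- pred$density[keep]
  ma <- pracma::trapz(gw, a)
  mb <- pracma::trapz(gw, b)
  if (ma <= 1e-10 || mb <= 1e-10) {
    stop("undefined score: a distribution has no mass below r_limit",
         call. = FALSE)
  }
  pracma::trapz(gw, pmin(a / ma, b / mb))
}

#' Rank pairing hypotheses against a recovered distribution
#'
#' Scores every hypothesis with [score_hypothesis()] and sorts by score
#' (ties broken by name). Calls: `consistent` at score >= `consistent_min`,
#' `excluded` at score <= `excluded_max`, otherwise `inconclusive`. The
#' default thresholds correspond to the overlap of two 0.15 nm-sd Gaussians
#' about 0.5 nm apart (~0.1): a few Angstrom of disagreement excludes.
#'
#' @param recovered A [distance_distribution()].
#' @param hypotheses List (>= 2) of `pairing_hypothesis` objects.
#' @param r_limit Comparison window bound (nm).
#' @param consistent_min,excluded_max Call thresholds; defaults 0.5 / 0.1.
#' @return Data frame with columns `name`, `score`, `call`, sorted by
#'   descending score.
#' @export
rank_hypotheses <- function(recovered, hypotheses, r_limit,
                            consistent_min = 0.5, excluded_max = 0.1) {
  if (length(hypotheses) < 2L) stop("give at least 2 hypotheses", call. = FALSE)
  names_h <- vapply(hypotheses, function(h) h$name, character(1))
  scores <- vapply(seq_along(hypotheses), function(i) {
    tryCatch(score_hypothesis(recovered, hypotheses[[i]], r_limit),
             error = function(e) {
               stop(sprintf("hypothesis '%s': %s", names_h[i],
                            conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1))
  ord <- order(-scores, names_h)
  call <- ifelse(scores >= consistent_min, "consistent",
                 ifelse(scores <= excluded_max, "excluded", "inconclusive"))
  data.frame(name = names_h[ord], score = scores[ord], call = call[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
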