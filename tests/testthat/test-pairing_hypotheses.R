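test_that("pair distributions sit at the configured site distances", {
  geom <- site_geometry()
  grid <- distance_grid()
  r <- as.numeric(grid)
  mean_of <- function(d) pracma::trapz(r, r * d$density)
  expect_equal(mean_of(pair_distribution(geom, "a1-b1", grid)), 4.1,
               tolerance = 0.01)
  expect_equal(mean_of(pair_distribution(geom, "a1-b2", grid)), 2.5,
               tolerance = 0.01)
  # symmetry aliases resolve to the same model
  expect_equal(pair_distribution(geom, "b1-a2", grid),
               pair_distribution(geom, "a1-b2", grid))
  expect_equal(pair_distribution(geom, "b1-b2", grid),
               pair_distribution(geom, "a1-a2", grid))
  expect_error(pair_distribution(geom, "a1-c9", grid), "unknown site pair")
  # sigma -> 0 limit concentrates on one grid step
  sharp <- site_geometry(sigma = 1e-4)
  d <- pair_distribution(sharp, "a1-a2", grid)
  near <- abs(r - 3.0) <= 0.0251
  expect_gt(pracma::trapz(r[near], d$density[near]), 0.99)
})

test_that("empirical ensemble distributions match their generating law", {
  grid <- distance_grid()
  r <- as.numeric(grid)
  two <- data.frame(frame = 1:2, source = "md1",
                    ax = 0, ay = 0, az = 0, bx = 2.0, by = 0, bz = 0)
  d <- empirical_pair_distribution(two, grid = grid, smoothing = 0.02)
  expect_equal(modal_distance(d), 2.0, tolerance = 0.026)

  withr::with_seed(3, {
    n <- 5000
    dist_true <- rnorm(n, 3.0, 0.1)
    fr <- data.frame(frame = seq_len(n), source = "md1",
                     ax = 0, ay = 0, az = 0, bx = dist_true, by = 0, bz = 0)
    d2 <- empirical_pair_distribution(fr, grid = grid)
    expect_equal(pracma::trapz(r, r * d2$density), 3.0, tolerance = 0.02)
  })

  # zero-weight sources drop out
  fr2 <- data.frame(frame = 1:4, source = rep(c("md1", "md2"), each = 2),
                    ax = 0, ay = 0, az = 0, bx = c(2, 2, 4, 4), by = 0, bz = 0)
  w10 <- empirical_pair_distribution(fr2, weights = c(md1 = 1, md2 = 0),
                                     grid = grid)
  only1 <- empirical_pair_distribution(fr2[fr2$source == "md1", ], grid = grid)
  expect_equal(w10$density, only1$density, tolerance = 1e-9)

  bad <- fr2
  bad$bx[3] <- "oops"
  expect_error(empirical_pair_distribution(bad, grid = grid), "row 3")
})

test_that("hypothesis composition is a normalized mixture", {
  grid <- distance_grid()
  g1 <- gaussian_distribution(grid, 2.5, 0.15)
  g2 <- gaussian_distribution(grid, 4.1, 0.15)
  same <- compose_hypothesis("same", list(
    list(distribution = g1, weight = 0.5),
    list(distribution = g1, weight = 0.5)
  ))
  expect_equal(same$predicted$density, g1$density, tolerance = 1e-12)

  r <- as.numeric(grid)
  mix <- compose_hypothesis("mix", list(
    list(distribution = g1, weight = 0.3),
    list(distribution = g2, weight = 0.7)
  ))
  m1 <- pracma::trapz(r, r * g1$density)
  m2 <- pracma::trapz(r, r * g2$density)
  expect_equal(pracma::trapz(r, r * mix$predicted$density),
               0.3 * m1 + 0.7 * m2, tolerance = 1e-9)
  expect_error(compose_hypothesis("none", list()), "non-empty")

  # the symmetric cross pairing superposes to a single 2.5 nm peak
  cross <- default_hypotheses()$cross
  expect_equal(modal_distance(cross$predicted), 2.5, tolerance = 0.026)
  dens <- cross$predicted$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1L
  expect_length(peaks[dens[peaks] > 0.1 * max(dens)], 1L)
})

test_that("overlap scoring behaves like an overlap coefficient", {
  grid <- distance_grid()
  g <- gaussian_distribution(grid, 2.5, 0.15)
  expect_equal(score_hypothesis(g, g, r_limit = 6), 1, tolerance = 1e-9)
  far <- gaussian_distribution(grid, 4.1, 0.15)
  expect_lt(score_hypothesis(g, far, r_limit = 6), 0.001)
  # symmetric in its arguments
  a <- gaussian_distribution(grid, 2.5, 0.2)
  b <- gaussian_distribution(grid, 2.8, 0.15)
  expect_equal(score_hypothesis(a, b, 6), score_hypothesis(b, a, 6),
               tolerance = 1e-12)
  expect_error(score_hypothesis(g, far, r_limit = 2.0), "no mass")
})

test_that("ranking orders hypotheses and applies the call thresholds", {
  grid <- distance_grid()
  rec <- gaussian_distribution(grid, 2.5, 0.12)
  hyps <- default_hypotheses()
  rk <- rank_hypotheses(rec, hyps, r_limit = reliability_limit(2))
  expect_identical(rk$name[1L], "cross")
  expect_identical(rk$call[rk$name == "both-catalytic"], "excluded")
  expect_false(any(rk$call[rk$name == "intra-monomer"] == "consistent"))

  # recovered equal to one hypothesis scores 1 and ranks first
  rec2 <- hyps$`intra-monomer`$predicted
  rk2 <- rank_hypotheses(rec2, hyps, r_limit = 6)
  expect_identical(rk2$name[1L], "intra-monomer")
  expect_equal(rk2$score[1L], 1, tolerance = 1e-9)

  expect_error(rank_hypotheses(rec, hyps["cross"], 6), "at least 2")
  expect_error(rank_hypotheses(rec, hyps, r_limit = 1.5),
               "hypothesis")
})
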