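test_that("occupancy state enforces simplex invariants", {
  expect_error(occupancy_state(0.5, 0.5, 0.5), "sum to 1")
  expect_error(occupancy_state(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  st <- occupancy_state(0.70, 0.21, 0.09)
  expect_equal(st$f0 + st$f1 + st$f2, 1)
})

test_that("infer_occupancy inverts the observable map exactly", {
  lab <- labeling_model(0.4, 1)
  st <- infer_occupancy(0.4 * 0.18 / 0.39, 0.39, lab)
  expect_equal(c(st$f0, st$f1, st$f2), c(0.70, 0.21, 0.09), tolerance = 1e-12)

  expect_equal(unlist(infer_occupancy(0, 0.5, lab)[c("f0", "f1", "f2")]),
               c(f0 = 0.5, f1 = 0.5, f2 = 0), tolerance = 1e-12)
  expect_equal(unlist(infer_occupancy(0.4, 2, lab)[c("f0", "f1", "f2")]),
               c(f0 = 0, f1 = 0, f2 = 1), tolerance = 1e-12)
  expect_error(infer_occupancy(0.5, 0.39, lab), "lambda")
  expect_error(infer_occupancy(0.1, 3, lab), "bound_signal")
})

test_that("round trip through observables is the identity on valid states", {
  lab <- labeling_model(0.37, 1)
  withr::with_seed(11, {
    for (i in 1:25) {
      st <- random_occupancy_state()
      if (st$f1 + 2 * st$f2 <= 0) next
      obs <- observables_from_state(st, lab)
      back <- infer_occupancy(obs$depth, obs$bound_signal, lab)
      expect_equal(c(back$f0, back$f1, back$f2), c(st$f0, st$f1, st$f2),
                   tolerance = 1e-12)
    }
  })
})

test_that("spin reduction thins labels binomially and composes", {
  st <- occupancy_state(0.2, 0.3, 0.5)
  expect_equal(apply_spin_reduction(st, 1), st)
  expect_equal(unlist(apply_spin_reduction(st, 0)[c("f0", "f1", "f2")]),
               c(f0 = 1, f1 = 0, f2 = 0))
  half <- apply_spin_reduction(occupancy_state(0, 0, 1), 0.5)
  expect_equal(c(half$f0, half$f1, half$f2), c(0.25, 0.5, 0.25))
  # multiplicative: s then s' equals s * s'
  a <- apply_spin_reduction(apply_spin_reduction(st, 0.8), 0.6)
  b <- apply_spin_reduction(st, 0.48)
  expect_equal(c(a$f0, a$f1, a$f2), c(b$f0, b$f1, b$f2), tolerance = 1e-12)
  # total probability conserved
  expect_equal(a$f0 + a$f1 + a$f2, 1, tolerance = 1e-12)
})

test_that("random-binding null is binomial at equal mean load", {
  expect_equal(random_binding_null(occupancy_state(1, 0, 0)),
               occupancy_state(1, 0, 0))
  expect_equal(random_binding_null(occupancy_state(0, 0, 1)),
               occupancy_state(0, 0, 1))
  null <- random_binding_null(occupancy_state(0.70, 0.21, 0.09))
  expect_equal(null$f2, 0.195^2, tolerance = 1e-12)
  # mean load preserved for arbitrary states
  withr::with_seed(3, {
    for (i in 1:20) {
      st <- random_occupancy_state()
      nl <- random_binding_null(st)
      expect_equal(nl$f1 + 2 * nl$f2, st$f1 + 2 * st$f2, tolerance = 1e-12)
    }
  })
})

test_that("cooperativity test flags excess double occupancy", {
  rep <- cooperativity_test(occupancy_state(0.70, 0.21, 0.09),
                            n_dimers = 5000L, n_boot = 1000L, seed = 1)
  expect_equal(rep$ratio, 0.09 / 0.195^2, tolerance = 1e-12)
  expect_identical(rep$verdict, "cooperative")
  expect_true(rep$ci_lo > 1 && rep$ci_lo <= rep$ratio)

  # anti-cooperative perturbation of the binomial p = 0.3 state
  anti <- cooperativity_test(occupancy_state(0.55, 0.42, 0.03),
                             n_dimers = 10000L, n_boot = 1000L, seed = 2)
  expect_identical(anti$verdict, "anti-cooperative")
  expect_error(cooperativity_test(occupancy_state(0.70, 0.21, 0.09), 50),
               "n_dimers")
})

test_that("binomial states are called indistinguishable in the majority", {
  st <- occupancy_state(0.49, 0.42, 0.09)  # exactly binomial, p = 0.3
  verdicts <- vapply(1:20, function(s) {
    cooperativity_test(st, n_dimers = 10000L, n_boot = 400L, seed = s)$verdict
  }, character(1))
  expect_gt(mean(verdicts == "indistinguishable"), 0.5)
})
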