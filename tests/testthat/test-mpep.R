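test_that("single-edge optimizer matches a dense grid argmax", {
  sch <- cycle_scheme(c(100, 1, 10), c(1, 2, 0.001))  # optimize k3 (edge 2)
  bounds <- c(1e-3, 1e6)
  res <- mpep_optimize_edge(sch, edge = 2, bounds = bounds)
  ora <- grid_argmax(sch, 2, bounds)
  expect_identical(res$boundary, ora$boundary)
  if (!res$boundary) {
    expect_equal(res$k_optimal, ora$k, tolerance = 1e-4)
    expect_gte(res$sigma_at_optimum_RT, ora$sigma * (1 - 1e-10))
  }
  expect_true(res$k_optimal >= bounds[1] && res$k_optimal <= bounds[2])
  expect_lte(res$sigma_at_optimum_RT, res$total_dissipation_RT * (1 + 1e-12))

  set.seed(505)
  for (i in 1:5) {
    sch <- rand_scheme(3, lo = -1, hi = 4)
    e <- sample(3, 1)
    res <- mpep_optimize_edge(sch, e, bounds = c(1e-4, 1e8))
    ora <- grid_argmax(sch, e, c(1e-4, 1e8), n = 3000)
    expect_identical(res$boundary, ora$boundary)
    if (!res$boundary) expect_equal(res$k_optimal, ora$k, tolerance = 1e-3)
    expect_gte(res$sigma_at_optimum_RT, ora$sigma * (1 - 1e-8))
  }
})

test_that("holding the step equilibrium constant yields an interior trade-off maximum", {
  # with the edge's equilibrium constant fixed, sigma_edge vanishes at both
  # extremes (rate-limiting edge: no flux; fast edge: local equilibrium),
  # so the maximum is interior - and must match the brute-force grid
  sch <- cycle_scheme(c(100, 1, 10), c(1, 2, 0.001))
  bounds <- c(1e-3, 1e6)
  res <- mpep_optimize_edge(sch, 2, bounds = bounds, hold_step_equilibrium = TRUE)
  expect_false(res$boundary)
  ora <- grid_argmax(sch, 2, bounds, n = 3000, hold = TRUE)
  expect_equal(res$k_optimal, ora$k, tolerance = 1e-4)
  expect_equal(res$sigma_at_optimum_RT, ora$sigma, tolerance = 1e-8)
  # sigma collapses toward zero at both endpoints relative to the optimum
  K0 <- sch$forward[2] / sch$reverse[2]
  for (k_end in bounds) {
    f <- sch$forward; r <- sch$reverse
    f[2] <- k_end; r[2] <- k_end / K0
    s_end <- solve_steady_state(cycle_scheme(f, r))$edge_sigma_RT[2]
    expect_lt(s_end, res$sigma_at_optimum_RT)
  }
})

test_that("the optimum beats the detailed-balance point of the edge", {
  sch <- cycle_scheme(c(100, 1, 10), c(1, 2, 0.001))
  res <- mpep_optimize_edge(sch, 2, bounds = c(1e-3, 1e6))
  # the k restoring detailed balance (prod fwd = prod rev) zeroes sigma
  k_db <- prod(sch$reverse) / (sch$forward[1] * sch$forward[3])
  f <- sch$forward; f[2] <- k_db
  st_db <- solve_steady_state(cycle_scheme(f, sch$reverse))
  expect_identical(st_db$edge_sigma_RT[2], 0)
  expect_gt(res$sigma_at_optimum_RT, 0)
})

test_that("time rescaling covaries the optimum exactly", {
  sch <- cycle_scheme(c(100, 1, 10), c(1, 2, 0.001))
  bounds <- c(1e-3, 1e6)
  res1 <- mpep_optimize_edge(sch, 2, bounds = bounds)
  sch2 <- cycle_scheme(2 * sch$forward, 2 * sch$reverse)
  res2 <- mpep_optimize_edge(sch2, 2, bounds = 2 * bounds)
  expect_equal(res2$k_optimal, 2 * res1$k_optimal, tolerance = 1e-10)
  expect_equal(res2$sigma_at_optimum_RT, 2 * res1$sigma_at_optimum_RT,
               tolerance = 1e-10)
})

test_that("boundary maxima are flagged, never silently interior", {
  sch <- toy3()
  # squeeze the search window away from the interior optimum
  res <- mpep_optimize_edge(sch, 2, bounds = c(1e-3, 1e-2))
  expect_true(res$boundary)
  expect_false(res$converged)
})

test_that("optimizer is deterministic", {
  sch <- cycle_scheme(c(100, 1, 10), c(1, 2, 0.001))
  r1 <- mpep_optimize_edge(sch, 2, bounds = c(1e-3, 1e6))
  r2 <- mpep_optimize_edge(sch, 2, bounds = c(1e-3, 1e6))
  expect_identical(r1$k_optimal, r2$k_optimal)
  expect_identical(r1$sigma_at_optimum_RT, r2$sigma_at_optimum_RT)
})

test_that("two-edge fixed point is order-invariant and self-consistent", {
  sch <- cycle_scheme(c(100, 1, 10, 5), c(1, 2, 0.001, 0.5))
  bounds <- c(1e-3, 1e6)
  pa <- mpep_optimize_pair(sch, c(2, 4), bounds = bounds)
  pb <- mpep_optimize_pair(sch, c(4, 2), bounds = bounds)
  expect_true(pa$converged)
  expect_true(pb$converged)
  ka <- sort(vapply(pa$results, `[[`, 0, "k_optimal"))
  kb <- sort(vapply(pb$results, `[[`, 0, "k_optimal"))
  expect_equal(ka, kb, tolerance = 1e-5)

  # at the fixed point, re-optimizing either edge alone moves k by < 1e-6 rel
  cur <- pa$scheme_at_optimum
  for (e in c(2L, 4L)) {
    re <- mpep_optimize_edge(cur, e, bounds = bounds)
    expect_equal(re$k_optimal, cur$forward[e], tolerance = 1e-6)
  }
})

test_that("fixed point is stable under 1% perturbations", {
  sch <- cycle_scheme(c(100, 1, 10, 5), c(1, 2, 0.001, 0.5))
  bounds <- c(1e-3, 1e6)
  p0 <- mpep_optimize_pair(sch, c(2, 4), bounds = bounds)
  k0 <- vapply(p0$results, `[[`, 0, "k_optimal")
  for (fac in c(0.99, 1.01)) {
    f <- sch$forward; f[c(2, 4)] <- k0 * fac
    pp <- mpep_optimize_pair(cycle_scheme(f, sch$reverse), c(2, 4), bounds = bounds)
    expect_true(pp$converged)
    expect_equal(vapply(pp$results, `[[`, 0, "k_optimal"), k0, tolerance = 1e-4)
  }
})

test_that("edge and bounds are validated", {
  sch <- toy3()
  expect_error(mpep_optimize_edge(sch, 5), "edge")
  expect_error(mpep_optimize_edge(sch, 2, bounds = c(1, 1)), "bounds")
  expect_error(mpep_optimize_edge(sch, 2, bounds = c(-1, 1)), "bounds")
  expect_error(mpep_optimize_pair(sch, c(2, 2)), "distinct")
})
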