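test_that("detailed-balance cycle is exactly at equilibrium", {
  sch <- cycle_scheme(c(1, 1), c(1, 1))
  st <- solve_steady_state(sch)
  expect_identical(st$probabilities, c(0.5, 0.5))
  expect_identical(st$J, 0)
  expect_identical(st$X_RT, 0)
  expect_identical(st$dissipation_RT, 0)
  expect_identical(st$edge_sigma_RT, c(0, 0))
  expect_equal(st$J_plus, st$J_minus)

  # balance enforced through a computed reverse constant, not round numbers
  f <- c(13.7, 0.44, 812)
  r <- c(3.1, 95, prod(f) / (3.1 * 95))
  st2 <- solve_steady_state(cycle_scheme(f, r))
  expect_identical(st2$J, 0)
  expect_identical(st2$dissipation_RT, 0)
  expect_identical(st2$edge_sigma_RT, c(0, 0, 0))
})

test_that("stationary distribution matches a dense eigenvector solve", {
  sch <- cycle_scheme(c(100, 50, 10), c(1, 2, 0.001))
  st <- solve_steady_state(sch)
  p_oracle <- oracle_steady_p(sch$forward, sch$reverse)
  expect_equal(st$probabilities, p_oracle, tolerance = 1e-12)
  # net flux from the solved p equals the edge flux on every edge
  for (i in 1:3) {
    j <- i %% 3 + 1
    expect_equal(sch$forward[i] * st$probabilities[i] -
                 sch$reverse[i] * st$probabilities[j],
                 st$J, tolerance = 1e-12)
  }
  # and the printed 3-state numerator/denominator form agrees
  k1 <- 100; k3 <- 50; k5 <- 10; k2 <- 1; k4 <- 2; k6 <- 0.001
  J9 <- (k1 * k3 * k5 - k2 * k4 * k6) /
    (k1 * (k3 + k4 + k5) + k2 * k4 + k2 * k5 + k3 * k5 + k6 * (k2 + k3 + k4))
  expect_equal(st$J, J9, tolerance = 1e-12)
})

test_that("closed-form flux matches the master-equation solve on random schemes", {
  set.seed(101)
  for (i in 1:300) {
    sch <- rand_scheme()
    st <- solve_steady_state(sch)
    p_oracle <- oracle_steady_p(sch$forward, sch$reverse)
    J_oracle <- sch$forward[1] * p_oracle[1] - sch$reverse[1] * p_oracle[2]
    cf <- closed_form_flux(sch)
    expect_equal(cf, st$J, tolerance = 1e-9)
    expect_equal(cf, J_oracle, tolerance = 1e-6)  # eigen route is less sharp
    expect_equal(sum(st$probabilities), 1, tolerance = 1e-12)
    expect_true(all(st$probabilities > 0 & st$probabilities < 1))
    expect_equal(st$J, st$J_plus - st$J_minus, tolerance = 1e-12)
    expect_identical(sign(st$J), sign(st$X_RT))
  }
})

test_that("one-way fluxes obey the cycle flux-force identity", {
  sch <- cycle_scheme(c(100, 50, 10), c(1, 2, 0.001))
  jpm <- one_way_fluxes(sch)
  st <- solve_steady_state(sch)
  expect_equal(unname(jpm["J_plus"] / jpm["J_minus"]), exp(st$X_RT),
               tolerance = 1e-9)
  expect_equal(unname(jpm["J_plus"] - jpm["J_minus"]), st$J, tolerance = 1e-12)

  # product rebinding switched off: backward cycling vanishes
  sch0 <- cycle_scheme(c(100, 50, 10), c(1, 2, 1e-12))
  jpm0 <- one_way_fluxes(sch0)
  expect_lt(jpm0["J_minus"] / jpm0["J_plus"], 1e-12)
})

test_that("edge entropy production is nonnegative, conservative, and convention-robust", {
  set.seed(202)
  for (i in 1:100) {
    sch <- rand_scheme()
    st <- solve_steady_state(sch)
    expect_true(all(st$edge_sigma_RT >= 0))
    expect_equal(sum(st$edge_sigma_RT), st$dissipation_RT, tolerance = 1e-9)
    # telescoping: the edge log-ratios sum to the cycle force
    n <- sch$n_states; p <- st$probabilities
    lr <- vapply(seq_len(n), function(e) {
      j <- e %% n + 1
      log(sch$forward[e] * p[e] / (sch$reverse[e] * p[j]))
    }, numeric(1))
    expect_equal(sum(lr), st$X_RT, tolerance = 1e-8)
  }

  # transition-matrix convention (W_ij p_j with W_ij the j -> i rate)
  # gives the same edge values after the index mapping
  sch <- cycle_scheme(c(100, 50, 10), c(1, 2, 0.001))
  st <- solve_steady_state(sch)
  W <- rate_matrix(sch$forward, sch$reverse)
  p <- st$probabilities
  for (e in 1:3) {
    a <- e; b <- e %% 3 + 1
    s_alt <- (W[b, a] * p[a] - W[a, b] * p[b]) * log(W[b, a] * p[a] / (W[a, b] * p[b]))
    expect_equal(edge_entropy_production(sch, st, e), s_alt, tolerance = 1e-12)
    expect_equal(edge_entropy_production(sch, st, e), st$edge_sigma_RT[e])
  }
  expect_error(edge_entropy_production(sch, st, 4), "edge")
  expect_error(edge_entropy_production(sch, st, 0), "edge")
})

test_that("net flux is nondecreasing in any single forward rate constant", {
  set.seed(303)
  for (i in 1:30) {
    sch <- rand_scheme()
    e <- sample(sch$n_states, 1)
    ks <- 10^seq(-2, 8, length.out = 40)
    J <- vapply(ks, function(k) {
      f <- sch$forward; f[e] <- k
      solve_steady_state(cycle_scheme(f, sch$reverse))$J
    }, numeric(1))
    expect_true(all(diff(J) >= -1e-9 * pmax(abs(J[-1]), abs(J[-length(J)]))))
  }
})
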