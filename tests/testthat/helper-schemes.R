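# Shared fixtures: random schemes and an independent dense linear-algebra
# oracle for the stationary distribution (eigenvector of the rate matrix),
# deliberately distinct from the package's spanning-tree route.

rand_scheme <- function(n = sample(2:4, 1), lo = -2, hi = 8,
                        with_substrate = FALSE, S = 1e-3) {
  f <- 10^runif(n, lo, hi)
  r <- 10^runif(n, lo, hi)
  sub <- if (with_substrate) list(k2nd = f[1] / S, conc = S) else NULL
  cycle_scheme(f, r, substrate = sub)
}

rate_matrix <- function(f, r) {
  n <- length(f)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    W[j, i] <- W[j, i] + f[i]
    W[i, j] <- W[i, j] + r[i]
  }
  diag(W) <- diag(W) - colSums(W)
  W
}

# stationary p as the kernel eigenvector of W (dense, independent route)
oracle_steady_p <- function(f, r) {
  W <- rate_matrix(f, r)
  ev <- eigen(W)
  k <- which.min(abs(ev$values))
  p <- Re(ev$vectors[, k])
  p / sum(p)
}

# GTH (Grassmann-Taksar-Heyman) elimination: the subtraction-free dense
# solve of the master equation, giving every stationary probability with
# componentwise relative accuracy regardless of conditioning
gth_p <- function(f, r) {
  n <- length(f)
  T <- matrix(0, n, n)                 # T[i, j]: rate i -> j
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    T[i, j] <- T[i, j] + f[i]
    T[j, i] <- T[j, i] + r[i]
  }
  for (k in n:2) {
    s <- sum(T[k, 1:(k - 1)])
    for (i in 1:(k - 1)) {
      if (T[i, k] == 0) next
      fac <- T[i, k] / s
      for (j in 1:(k - 1)) if (j != i) T[i, j] <- T[i, j] + fac * T[k, j]
    }
  }
  p <- numeric(n)
  p[1] <- 1
  for (k in 2:n) {
    s <- sum(T[k, 1:(k - 1)])
    p[k] <- sum(p[1:(k - 1)] * T[1:(k - 1), k]) / s
  }
  p / sum(p)
}

# brute-force oracle for the partial-EP maximizer: dense log-spaced grid
# argmax of the edge sigma, then a fine second-stage grid across the two
# neighboring cells (pure enumeration, no local model)
grid_argmax <- function(scheme, edge, bounds, n = 1e4, hold = FALSE) {
  K0 <- scheme$forward[edge] / scheme$reverse[edge]
  sig_at <- function(k) {
    f <- scheme$forward; r <- scheme$reverse
    f[edge] <- k
    if (hold) r[edge] <- k / K0
    solve_steady_state(cycle_scheme(f, r))$edge_sigma_RT[edge]
  }
  lg <- seq(log10(bounds[1]), log10(bounds[2]), length.out = n)
  sig <- vapply(10^lg, sig_at, numeric(1))
  i <- which.max(sig)
  if (i %in% c(1L, n))
    return(list(k = 10^lg[i], sigma = sig[i], boundary = TRUE))
  lg2 <- seq(lg[i - 1L], lg[i + 1L], length.out = 1000)
  sig2 <- vapply(10^lg2, sig_at, numeric(1))
  list(k = 10^lg2[which.max(sig2)], sigma = max(sig2), boundary = FALSE)
}

# a forward-driven 3-state workhorse used across files
toy3 <- function() cycle_scheme(c(100, 50, 10), c(1, 2, 0.001),
                                substrate = list(k2nd = 1e5, conc = 1e-3))
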