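# King-Altman / Hill diagram machinery for unicyclic schemes.
#
# For a single cycle of N states the stationary weight of state j is the sum
# over the N directed spanning trees rooted at j: cut one edge m, then orient
# every remaining edge toward j along the resulting path. The stationary
# distribution is p_j = Sigma_j / sum(Sigma), and the net cycle flux is
# J = (prod k_fwd - prod k_rev) / sum(Sigma).

# Directed spanning-tree sums Sigma_j, j = 1..N. Works for any N >= 2 and
# tolerates zero entries (used internally for concentration limits).
ka_state_weights <- function(fwd, rev) {
  n <- length(fwd)
  vapply(seq_len(n), function(j) {
    total <- 0
    for (m in seq_len(n)) {        # cut edge m; path starts at state m+1
      s <- m %% n + 1L
      q <- (j - s) %% n            # position of j along the path
      term <- 1
      for (e in seq_len(n)) {
        if (e == m) next
        pe <- (e - s) %% n
        term <- term * if (pe < q) fwd[e] else rev[e]
      }
      total <- total + term
    }
    total
  }, numeric(1))
}

ka_denominator <- function(fwd, rev) sum(ka_state_weights(fwd, rev))

# d Sigma / d fwd[1]: the sum over spanning trees that use edge 1 in the
# forward direction, with that factor divided out. Enumerated directly
# (not by differencing Sigma) to avoid catastrophic cancellation when the
# remaining tree terms dwarf the coefficient.
ka_denominator_dfwd1 <- function(fwd, rev) {
  n <- length(fwd)
  total <- 0
  for (j in seq_len(n)) {
    for (m in seq_len(n)) {
      if (m == 1L) next            # edge 1 must be present in the tree
      s <- m %% n + 1L
      q <- (j - s) %% n
      if (!(((1L - s) %% n) < q)) next   # and oriented forward
      term <- 1
      for (e in seq_len(n)) {
        if (e == m || e == 1L) next
        pe <- (e - s) %% n
        term <- term * if (pe < q) fwd[e] else rev[e]
      }
      total <- total + term
    }
  }
  total
}

#' Closed-form net cycle flux
#'
#' The King-Altman closed form for the steady-state net flux per enzyme,
#' `J = (prod k_fwd - prod k_rev) / Sigma`, with the denominator written out
#' explicitly for 2-, 3-, and 4-state cycles:
#'
#' * 2-state: `Sigma = k1 + k2 + k3 + k4`
#' * 3-state: `Sigma = k1(k3 + k4 + k5) + k2 k4 + k2 k5 + k3 k5 + k6(k2 + k3 + k4)`
#' * 4-state: `Sigma = Sigma1 + Sigma2 + Sigma3 + Sigma4` with
#'   `Sigma1 = k2k4k6 + k2k4k7 + k2k5k7 + k3k5k7`,
#'   `Sigma2 = k1k5k7 + k4k6k8 + k1k4k6 + k1k4k7`,
#'   `Sigma3 = k1k3k7 + k2k6k8 + k3k6k8 + k1k3k6`,
#'   `Sigma4 = k2k4k8 + k1k3k5 + k3k5k8 + k2k5k8`
#'
#' Each `Sigma_j` is the directed-spanning-tree sum for state `j`; the terms
#' above follow from cutting each cycle edge in turn and orienting the
#' remaining edges toward `j`. For `N > 4` the general spanning-tree sum is
#' used. [solve_steady_state()] must agree with this value to high relative
#' accuracy; the package tests enforce 1e-9.
#'
#' @param scheme a [cycle_scheme()].
#' @return net flux `J` in s^-1 per enzyme.
#' @export
closed_form_flux <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  f <- scheme$forward; r <- scheme$reverse
  num <- prod(f) - prod(r)
  den <- switch(as.character(scheme$n_states),
    "2" = f[1] + r[1] + f[2] + r[2],
    "3" = {
      k1 <- f[1]; k3 <- f[2]; k5 <- f[3]
      k2 <- r[1]; k4 <- r[2]; k6 <- r[3]
      k1 * (k3 + k4 + k5) + k2 * k4 + k2 * k5 + k3 * k5 + k6 * (k2 + k3 + k4)
    },
    "4" = {
      k1 <- f[1]; k3 <- f[2]; k5 <- f[3]; k7 <- f[4]
      k2 <- r[1]; k4 <- r[2]; k6 <- r[3]; k8 <- r[4]
      (k2 * k4 * k6 + k2 * k4 * k7 + k2 * k5 * k7 + k3 * k5 * k7) +
      (k1 * k5 * k7 + k4 * k6 * k8 + k1 * k4 * k6 + k1 * k4 * k7) +
      (k1 * k3 * k7 + k2 * k6 * k8 + k3 * k6 * k8 + k1 * k3 * k6) +
      (k2 * k4 * k8 + k1 * k3 * k5 + k3 * k5 * k8 + k2 * k5 * k8)
    },
    ka_denominator(f, r))
  num / den
}
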