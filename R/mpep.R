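# Maximum partial entropy production (MPEP) in a chosen transition.
#
# The partial entropy production of one edge has an interior maximum as a
# function of that edge's forward rate constant: pushing k up raises the
# edge flux but erodes the edge affinity (at very large k the edge
# approaches local equilibrium and its sigma falls back toward zero). No
# unimodality is assumed: a coarse logarithmic grid locates the global
# bracket before golden-section refinement on log10(k).

sigma_edge_at <- function(scheme, edge, k, hold_step_equilibrium = FALSE, K0 = NULL) {
  f <- scheme$forward; r <- scheme$reverse
  f[edge] <- k
  if (hold_step_equilibrium) r[edge] <- k / K0
  s2 <- cycle_scheme(f, r, substrate = scheme$substrate,
                     product = scheme$product,
                     temperature = scheme$temperature, name = scheme$name)
  st <- solve_steady_state(s2)
  list(sigma = st$edge_sigma_RT[edge], total = st$dissipation_RT)
}

#' Maximize the partial entropy production of one transition
#'
#' Varies the forward microscopic rate constant of the chosen edge, holding
#' its reverse constant and all other constants fixed (so the step
#' equilibrium constant changes freely as a consequence), and returns the
#' value maximizing that edge's partial entropy production at steady state.
#' Optionally the step equilibrium constant can be held fixed instead,
#' co-varying the reverse constant; this is not the default.
#'
#' The search is a coarse logarithmic grid over `bounds` (global bracketing;
#' unimodality is not assumed) followed by golden-section refinement on
#' `log10 k`. A maximum landing on a search boundary is flagged via
#' `boundary = TRUE` rather than reported as an interior optimum. The
#' procedure is deterministic: identical inputs give identical results.
#'
#' @param scheme a [cycle_scheme()].
#' @param edge edge index in `1..N`.
#' @param bounds length-2 numeric search interval for the forward constant
#'   (s^-1); default `c(1e-6, 1e12)` spans the physically plausible
#'   elementary-step range.
#' @param n_grid number of coarse log-spaced bracketing points.
#' @param tol relative tolerance on `k` at which refinement stops.
#' @param hold_step_equilibrium logical; co-vary the reverse constant so the
#'   step equilibrium constant stays fixed (default `FALSE`).
#' @return an object of class `mpep_result`: `edge`, `k_optimal`,
#'   `sigma_at_optimum_RT`, `total_dissipation_RT`, `n_evaluations`,
#'   `converged`, `boundary`, `bounds`.
#' @examples
#' sch <- cycle_scheme(c(100, 50, 10), c(1, 2, 0.001))
#' mpep_optimize_edge(sch, edge = 2, bounds = c(1e-3, 1e6))
#' @export
mpep_optimize_edge <- function(scheme, edge, bounds = c(1e-6, 1e12),
                               n_grid = 400L, tol = 1e-8,
                               hold_step_equilibrium = FALSE) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  n <- scheme$n_states
  if (edge < 1 || edge > n || edge != round(edge))
    stop(sprintf("edge must be in 1..%d", n), call. = FALSE)
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop("bounds must be an increasing positive pair", call. = FALSE)
  K0 <- scheme$forward[edge] / scheme$reverse[edge]

  n_eval <- 0L
  fobj <- function(lk) {
    n_eval <<- n_eval + 1L
    sigma_edge_at(scheme, edge, 10^lk, hold_step_equilibrium, K0)$sigma
  }

  lg <- seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
  vals <- vapply(lg, fobj, numeric(1))
  imax <- which.max(vals)
  boundary <- imax == 1L || imax == n_grid

  if (boundary) {
    lopt <- lg[imax]
  } else {
    # golden-section on log10(k) inside the bracketing cell pair
    gr <- (sqrt(5) - 1) / 2
    a <- lg[imax - 1L]; b <- lg[imax + 1L]
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- fobj(x1); f2 <- fobj(x2)
    while ((b - a) > tol / log(10)) {   # width in log10 ~ relative tol in k
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- fobj(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- fobj(x1)
      }
    }
    lopt <- if (f1 > f2) x1 else x2
  }

  k_opt <- 10^lopt
  at <- sigma_edge_at(scheme, edge, k_opt, hold_step_equilibrium, K0)
  structure(
    list(edge = as.integer(edge), k_optimal = k_opt,
         sigma_at_optimum_RT = at$sigma,
         total_dissipation_RT = at$total,
         n_evaluations = n_eval + 1L,
         converged = !boundary, boundary = boundary,
         bounds = bounds,
         hold_step_equilibrium = hold_step_equilibrium),
    class = "mpep_result")
}

#' @export
print.mpep_result <- function(x, ...) {
  cat(sprintf("<mpep_result: edge %d>\n", x$edge))
  cat(sprintf("  k_optimal   = %.6g s^-1%s\n", x$k_optimal,
              if (x$boundary) "  [boundary maximum]" else ""))
  cat(sprintf("  sigma/RT    = %.6g s^-1 (total diss/RT = %.6g)\n",
              x$sigma_at_optimum_RT, x$total_dissipation_RT))
  cat(sprintf("  evaluations = %d\n", x$n_evaluations))
  invisible(x)
}

#' Self-consistent two-edge MPEP optimization
#'
#' Alternately maximizes the partial entropy production of two distinct
#' transitions, each time re-optimizing one forward constant with the other
#' held at its current optimum, until both optimal constants move by less
#' than `tol` relative between outer iterations (or `max_outer` is reached,
#' in which case `converged = FALSE` is reported, never raised silently).
#'
#' @param scheme a [cycle_scheme()].
#' @param edges length-2 vector of distinct edge indices.
#' @param bounds search interval applied to both edges.
#' @param tol relative movement threshold declaring the fixed point.
#' @param max_outer maximum number of outer sweeps.
#' @param ... passed to [mpep_optimize_edge()].
#' @return an object of class `mpep_pair_result`: `results` (list of two
#'   [mpep_optimize_edge()] records), `n_outer_iterations`, `converged`.
#' @export
mpep_optimize_pair <- function(scheme, edges, bounds = c(1e-6, 1e12),
                               tol = 1e-6, max_outer = 100L, ...) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (length(edges) != 2L || edges[1] == edges[2])
    stop("edges must be two distinct indices", call. = FALSE)

  cur <- scheme
  k_prev <- c(NA_real_, NA_real_)
  res <- vector("list", 2L)
  converged <- FALSE
  iter <- 0L
  while (iter < max_outer) {
    iter <- iter + 1L
    for (e in 1:2) {
      res[[e]] <- mpep_optimize_edge(cur, edges[e], bounds = bounds, ...)
      f <- cur$forward; f[edges[e]] <- res[[e]]$k_optimal
      cur <- cycle_scheme(f, cur$reverse, substrate = cur$substrate,
                          product = cur$product,
                          temperature = cur$temperature, name = cur$name)
    }
    k_now <- c(res[[1]]$k_optimal, res[[2]]$k_optimal)
    if (!any(is.na(k_prev)) &&
        all(abs(k_now - k_prev) <= tol * k_prev)) {
      converged <- TRUE
      break
    }
    k_prev <- k_now
  }

  structure(
    list(results = res, edges = as.integer(edges),
         n_outer_iterations = iter, converged = converged,
         scheme_at_optimum = cur),
    class = "mpep_pair_result")
}

#' @export
print.mpep_pair_result <- function(x, ...) {
  cat(sprintf("<mpep_pair_result: edges %d & %d, %d outer iterations, %s>\n",
              x$edges[1], x$edges[2], x$n_outer_iterations,
              if (x$converged) "converged" else "NOT converged"))
  for (r in x$results)
    cat(sprintf("  edge %d: k_opt = %.6g, sigma/RT = %.6g\n",
                r$edge, r$k_optimal, r$sigma_at_optimum_RT))
  invisible(x)
}
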