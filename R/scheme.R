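#' Construct a unicyclic reversible kinetic scheme
#'
#' A `cycle_scheme` represents a single closed loop of `N` enzyme states
#' (E, ES, EZ, EP, ...) connected by reversible first-order transitions,
#' traversed once per catalytic event. States are numbered `1..N`
#' counterclockwise; edge `i` connects state `i` to state `i + 1` (mod `N`).
#' Forward (counterclockwise) rate constants are the odd-indexed microscopic
#' constants k1, k3, k5, k7 and reverse constants the even-indexed k2, k4,
#' k6, k8, all in s^-1.
#'
#' Ligand-binding transitions are pseudo-first-order: for substrate binding
#' E + S -> ES the stored first-order constant is `k1 = k1* [S]`, with `k1*`
#' the second-order constant (M^-1 s^-1). Declaring the substrate and
#' (optionally) product binding edges keeps the `[S] -> Inf` and `[S] -> 0`
#' limits used for kcat and kcat/KM well defined. The substrate-binding edge
#' is edge 1 (forward direction); the product-binding edge is edge `N`
#' (reverse direction, product rebinding `E + P -> EP`).
#'
#' @param forward numeric vector of forward rate constants (s^-1), one per
#'   edge, length `N >= 2` (k1, k3, k5, k7 for N = 4).
#' @param reverse numeric vector of reverse rate constants (s^-1), same
#'   length (k2, k4, k6, k8).
#' @param substrate optional list `list(k2nd = , conc = )` declaring the
#'   second-order substrate-binding constant (M^-1 s^-1) and `[S]` (M) for
#'   edge 1. If `forward[1]` is `NA` it is filled in as `k2nd * conc`;
#'   otherwise consistency `forward[1] == k2nd * conc` is enforced.
#' @param product optional list `list(k2nd = , conc = )` declaring product
#'   rebinding on the reverse direction of edge `N`; same consistency rule
#'   against `reverse[N]`.
#' @param temperature absolute temperature in kelvin (default 298.15).
#' @param name optional identifier carried through summaries.
#'
#' @return an object of class `cycle_scheme`.
#' @examples
#' sch <- cycle_scheme(forward = c(100, 50, 10), reverse = c(1, 2, 0.001))
#' solve_steady_state(sch)
#' @export
cycle_scheme <- function(forward, reverse, substrate = NULL, product = NULL,
                         temperature = 298.15, name = NULL) {
  forward <- as.numeric(forward)
  reverse <- as.numeric(reverse)
  n <- length(forward)
  if (n < 2L)
    stop("a unicyclic scheme needs at least 2 states", call. = FALSE)
  if (length(reverse) != n)
    stop("forward and reverse rate vectors must have equal length", call. = FALSE)

  if (!is.null(substrate)) {
    substrate <- check_binding(substrate, "substrate")
    k1 <- substrate$k2nd * substrate$conc
    if (is.na(forward[1])) forward[1] <- k1
    else if (abs(forward[1] - k1) > 1e-8 * max(forward[1], k1))
      stop("substrate binding inconsistent: forward[1] != k2nd * [S]", call. = FALSE)
  }
  if (!is.null(product)) {
    product <- check_binding(product, "product")
    kN <- product$k2nd * product$conc
    if (is.na(reverse[n])) reverse[n] <- kN
    else if (abs(reverse[n] - kN) > 1e-8 * max(reverse[n], kN))
      stop("product binding inconsistent: reverse[N] != k2nd * [P]", call. = FALSE)
  }

  if (any(!is.finite(forward)) || any(!is.finite(reverse)) ||
      any(forward <= 0) || any(reverse <= 0))
    stop("all rate constants must be strictly positive and finite", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)

  structure(
    list(n_states = n, forward = forward, reverse = reverse,
         substrate = substrate, product = product,
         temperature = temperature, name = name),
    class = "cycle_scheme")
}

check_binding <- function(b, what) {
  if (!is.list(b) || is.null(b$k2nd) || is.null(b$conc))
    stop(sprintf("%s binding must be list(k2nd = , conc = )", what), call. = FALSE)
  b$k2nd <- as.numeric(b$k2nd); b$conc <- as.numeric(b$conc)
  if (!is.finite(b$k2nd) || b$k2nd <= 0)
    stop(sprintf("%s second-order constant must be positive", what), call. = FALSE)
  if (!is.finite(b$conc) || b$conc <= 0)
    stop(sprintf("%s concentration must be positive", what), call. = FALSE)
  b
}

#' @export
print.cycle_scheme <- function(x, ...) {
  cat(sprintf("<cycle_scheme%s: %d states, T = %.2f K>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_states, x$temperature))
  tab <- rbind(forward = x$forward, reverse = x$reverse)
  colnames(tab) <- paste0("edge", seq_len(x$n_states))
  print(tab)
  cat(sprintf("X/RT = %.6g\n", thermodynamic_force(x)))
  invisible(x)
}

#' Step and overall equilibrium constants
#'
#' The step equilibrium constant of edge `i` is `K_i = k_fwd(i)/k_rev(i)`;
#' the overall cycle constant is their product, `K = prod(K_i)`, so that the
#' thermodynamic force is `X = RT ln K`.
#'
#' @param scheme a [cycle_scheme()].
#' @return numeric vector of the `K_i` with attribute `overall` holding `K`.
#' @export
step_equilibrium_constants <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  K <- scheme$forward / scheme$reverse
  attr(K, "overall") <- exp(sum(log(scheme$forward)) - sum(log(scheme$reverse)))
  K
}

#' Thermodynamic force of the cycle
#'
#' The affinity driving net cycling, `X = RT ln(prod k_fwd / prod k_rev)`.
#' Computed as a sum of logarithms so rate constants spanning many orders of
#' magnitude do not overflow. Sign convention: `X > 0` means net forward
#' (substrate-consuming, counterclockwise) drive, equivalently `Gamma < K_eq`
#' with `Gamma` the mass-action ratio, so `X = RT ln(K_eq / Gamma)`.
#'
#' @param scheme a [cycle_scheme()].
#' @param units `"RT"` (dimensionless X/RT, default) or `"J_per_mol"`
#'   (multiplies by R T with R = 8.314 J mol^-1 K^-1).
#' @param R gas constant, J mol^-1 K^-1.
#' @return numeric force.
#' @export
thermodynamic_force <- function(scheme, units = c("RT", "J_per_mol"), R = 8.314) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  units <- match.arg(units)
  x <- sum(log(scheme$forward)) - sum(log(scheme$reverse))
  if (abs(x) < 1e-12) x <- 0       # detailed-balance cycles report exact zero
  if (units == "RT") x else x * R * scheme$temperature
}

#' Mass-action ratio Gamma = [P]/[S]
#'
#' Derivable only when both substrate- and product-binding edges are declared.
#' @param scheme a [cycle_scheme()].
#' @return numeric `Gamma`.
#' @export
mass_action_ratio <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (is.null(scheme$substrate) || is.null(scheme$product))
    stop("Gamma requires both substrate- and product-binding declarations", call. = FALSE)
  scheme$product$conc / scheme$substrate$conc
}

#' Equilibrium constant of the catalyzed reaction
#'
#' `K_eq = [P]_eq/[S]_eq`, obtained from the bare-cycle constant built with
#' the second-order binding constants in place of the composite
#' pseudo-first-order rates: at equilibrium the cycle product of
#' concentration-corrected rate ratios equals one. Satisfies
#' `X = RT ln(K_eq/Gamma)`.
#'
#' @param scheme a [cycle_scheme()] with both binding edges declared.
#' @return numeric `K_eq` (dimensionless for a uni-uni reaction).
#' @export
equilibrium_constant <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (is.null(scheme$substrate) || is.null(scheme$product))
    stop("K_eq requires both substrate- and product-binding declarations", call. = FALSE)
  lf <- sum(log(scheme$forward)) - log(scheme$forward[1]) + log(scheme$substrate$k2nd)
  n <- scheme$n_states
  lr <- sum(log(scheme$reverse)) - log(scheme$reverse[n]) + log(scheme$product$k2nd)
  exp(lf - lr)
}

#' Re-evaluate a scheme at different ligand concentrations
#'
#' Rescales the composite pseudo-first-order binding rates to new substrate
#' and/or product concentrations, leaving the second-order constants and all
#' purely conformational rates untouched. Only declared binding edges can be
#' rescaled.
#'
#' @param scheme a [cycle_scheme()].
#' @param S new substrate concentration (M), or `NULL` to keep.
#' @param P new product concentration (M), or `NULL` to keep.
#' @return a new `cycle_scheme`.
#' @export
at_concentrations <- function(scheme, S = NULL, P = NULL) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  fwd <- scheme$forward; rev <- scheme$reverse
  sub <- scheme$substrate; prod <- scheme$product
  if (!is.null(S)) {
    if (is.null(sub)) stop("no substrate-binding edge declared", call. = FALSE)
    sub$conc <- S
    fwd[1] <- sub$k2nd * S
  }
  if (!is.null(P)) {
    if (is.null(prod)) stop("no product-binding edge declared", call. = FALSE)
    prod$conc <- P
    rev[scheme$n_states] <- prod$k2nd * P
  }
  cycle_scheme(fwd, rev, substrate = sub, product = prod,
               temperature = scheme$temperature, name = scheme$name)
}
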