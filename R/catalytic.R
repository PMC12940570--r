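# Catalytic parameters from microscopic rate constants.
#
# kcat is the saturating-substrate, vanishing-product limit of the net flux
# per enzyme: [S] -> Inf scales only the composite binding rate k1 = k1*[S],
# and [P] -> 0 sends the product-rebinding rate (the reverse constant of the
# last edge) to zero. Because the King-Altman denominator is multilinear in
# each rate constant, both limits are available in closed form:
#
#   kcat        = prod(k_fwd[2..N]) / A,   A = d Sigma / d k1  at rev[N] = 0
#   kcat/KM     = k1* prod(k_fwd[2..N]) / Sigma(k1 = 0, rev[N] = 0)
#
# which for N = 2..4 reduce to the familiar textbook expressions coded in
# kcat_closed_form() / specificity_closed_form().

# exact [S]->Inf, [P]->0 flux limit via the multilinearity of Sigma
kcat_limit <- function(fwd, rev) {
  n <- length(fwd)
  rev[n] <- 0
  prod(fwd[-1]) / ka_denominator_dfwd1(fwd, rev)
}

# exact low-[S] slope lim J/[S] at [P] = 0 (second-order, M^-1 s^-1)
specificity_limit <- function(fwd, rev, k1_2nd) {
  n <- length(fwd)
  rev[n] <- 0
  f0 <- fwd; f0[1] <- 0
  k1_2nd * prod(fwd[-1]) / ka_denominator(f0, rev)
}

#' Closed-form turnover number
#'
#' Printed closed forms of `kcat` for 2-, 3-, and 4-state cycles (forward
#' constants k1, k3, k5, k7; reverse k2, k4, k6, k8):
#'
#' * 2-state: `kcat = k3`
#' * 3-state: `kcat = k5 / (1 + k4/k3 + k5/k3)`
#' * 4-state: `kcat = k3 k5 k7 / (k5k7 + k4k6 + k4k7 + k3k7 + k3k6 + k3k5)`,
#'   equivalently `k3 / (1 + k3/k7 + (k3/k5)(1 + 1/K2)(1 + (k5/k7)/K3))`
#'   with step equilibrium constants `K2 = k3/k4`, `K3 = k5/k6`.
#'
#' Each equals the `[S] -> Inf`, `[P] -> 0` limit of the net steady-state
#' flux per enzyme ([kcat_operational()]), which is also used for `N > 4`.
#'
#' @param scheme a [cycle_scheme()].
#' @return `kcat` in s^-1.
#' @export
kcat_closed_form <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  f <- scheme$forward; r <- scheme$reverse
  switch(as.character(scheme$n_states),
    "2" = f[2],
    "3" = f[3] / (1 + r[2] / f[2] + f[3] / f[2]),
    "4" = {
      k3 <- f[2]; k5 <- f[3]; k7 <- f[4]; k4 <- r[2]; k6 <- r[3]
      k3 * k5 * k7 /
        (k5 * k7 + k4 * k6 + k4 * k7 + k3 * k7 + k3 * k6 + k3 * k5)
    },
    stop("closed-form kcat is provided for 2-4 states; use kcat_operational()",
         call. = FALSE))
}

#' Closed-form specificity constant kcat/KM
#'
#' Printed closed forms of the second-order specificity constant
#' (M^-1 s^-1), with `k1*` the second-order substrate-binding constant:
#'
#' * 2-state: `kcat/KM = k1* k3 / (k2 + k3)`
#' * 3-state: `kcat/KM = k1* k3 k5 / (k2k4 + k2k5 + k3k5)`
#' * 4-state: `kcat/KM = k1* k3 k5 k7 / (k2k4k6 + k2k4k7 + k2k5k7 + k3k5k7)`
#'
#' Each equals the `[S] -> 0`, `[P] -> 0` slope of `J` versus `[S]`
#' ([specificity_operational()]).
#'
#' @param scheme a [cycle_scheme()] with a substrate-binding declaration.
#' @return `kcat/KM` in M^-1 s^-1.
#' @export
specificity_closed_form <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (is.null(scheme$substrate))
    stop("kcat/KM requires a substrate-binding declaration (second-order k1*)",
         call. = FALSE)
  k1s <- scheme$substrate$k2nd
  f <- scheme$forward; r <- scheme$reverse
  switch(as.character(scheme$n_states),
    "2" = k1s * f[2] / (r[1] + f[2]),
    "3" = k1s * f[2] * f[3] /
            (r[1] * r[2] + r[1] * f[3] + f[2] * f[3]),
    "4" = {
      k3 <- f[2]; k5 <- f[3]; k7 <- f[4]
      k2 <- r[1]; k4 <- r[2]; k6 <- r[3]
      k1s * k3 * k5 * k7 /
        (k2 * k4 * k6 + k2 * k4 * k7 + k2 * k5 * k7 + k3 * k5 * k7)
    },
    stop("closed-form kcat/KM is provided for 2-4 states; use specificity_operational()",
         call. = FALSE))
}

#' Operational turnover number (flux limit)
#'
#' `kcat` as the exact `[S] -> Inf`, `[P] -> 0` limit of the net cycle flux,
#' evaluated analytically through the multilinearity of the King-Altman
#' denominator. Defined for any cycle size; the route is independent of the
#' printed closed forms and is used to cross-check them.
#'
#' @param scheme a [cycle_scheme()].
#' @return `kcat` in s^-1.
#' @export
kcat_operational <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  kcat_limit(scheme$forward, scheme$reverse)
}

#' Operational specificity constant (low-substrate slope)
#'
#' `kcat/KM` as the exact `[S] -> 0`, `[P] -> 0` slope of `J` versus `[S]`.
#'
#' @param scheme a [cycle_scheme()] with a substrate-binding declaration.
#' @return `kcat/KM` in M^-1 s^-1.
#' @export
specificity_operational <- function(scheme) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (is.null(scheme$substrate))
    stop("kcat/KM requires a substrate-binding declaration (second-order k1*)",
         call. = FALSE)
  specificity_limit(scheme$forward, scheme$reverse, scheme$substrate$k2nd)
}

#' Full kinetic and thermodynamic summary of one enzyme
#'
#' Computes `kcat`, `KM = kcat / (kcat/KM)`, the specificity constant
#' `kcat/KM`, the steady-state dissipation over RT at the declared working
#' concentrations, and the backward-flux diagnostic `kcat/J`. `kcat` and
#' `kcat/KM` use the printed closed forms for 2-4 states (the operational
#' flux limits for larger cycles); closed-form and operational routes are
#' algebraically identical and are cross-checked in the package tests.
#'
#' A scheme driven backwards (`X < 0`) is flagged via `backward_driven`,
#' not rejected: its forward-defined kcat and KM remain meaningful.
#'
#' @param scheme a [cycle_scheme()] with a substrate-binding declaration.
#' @param class_label one of `"specialist"`, `"generalist"`, `"mutant"`,
#'   `"wild-type"`, `"unknown"`.
#' @param evo_distance optional evolutionary distance (substitutions/site).
#' @return an object of class `kinetic_summary`.
#' @export
catalytic_parameters <- function(scheme, class_label = "unknown",
                                 evo_distance = NA_real_) {
  stopifnot(inherits(scheme, "cycle_scheme"))
  if (is.null(scheme$substrate))
    stop("catalytic_parameters requires a substrate-binding declaration",
         call. = FALSE)
  class_label <- match.arg(class_label,
    c("unknown", "specialist", "generalist", "mutant", "wild-type"))

  kcat <- if (scheme$n_states <= 4L) kcat_closed_form(scheme)
          else kcat_operational(scheme)
  spec <- if (scheme$n_states <= 4L) specificity_closed_form(scheme)
          else specificity_operational(scheme)
  st <- solve_steady_state(scheme)

  structure(
    list(name = if (is.null(scheme$name)) NA_character_ else scheme$name,
         n_states = scheme$n_states,
         kcat = kcat, KM = kcat / spec, kcat_KM = spec,
         dissipation_RT = st$dissipation_RT,
         J = st$J, J_plus = st$J_plus, J_minus = st$J_minus,
         kcat_over_J = if (st$J != 0) kcat / st$J else Inf,
         X_RT = st$X_RT,
         backward_driven = st$X_RT < 0,
         class_label = class_label,
         evo_distance = evo_distance),
    class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("<kinetic_summary%s>\n",
              if (is.na(x$name)) "" else paste0(" ", x$name)))
  cat(sprintf("  kcat      = %.6g s^-1\n", x$kcat))
  cat(sprintf("  KM        = %.6g M\n", x$KM))
  cat(sprintf("  kcat/KM   = %.6g M^-1 s^-1\n", x$kcat_KM))
  cat(sprintf("  diss/RT   = %.6g s^-1   (X/RT = %.4g)\n",
              x$dissipation_RT, x$X_RT))
  cat(sprintf("  kcat/J    = %.6g\n", x$kcat_over_J))
  if (x$backward_driven) cat("  [flagged: backward-driven, X < 0]\n")
  invisible(x)
}
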