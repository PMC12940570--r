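# Dissipation-plane scaling fits across enzyme ensembles.
#
# The empirical regularity being quantified: across enzymes spanning many
# orders of magnitude, dissipation/(RT) scales as a power law of the
# catalytic parameters, diss/RT = 10^a (kcat/KM)^b, i.e. a straight line in
# log10-log10 coordinates, and the points are near-planar in
# (log10 kcat, log10 KM, log10 diss/RT) space.

records_frame <- function(records) {
  if (inherits(records, "kinetic_summary")) records <- list(records)
  if (is.data.frame(records)) return(records)
  if (is.list(records) && all(vapply(records, inherits, logical(1), "kinetic_summary"))) {
    return(do.call(rbind, lapply(records, function(r)
      data.frame(name = r$name, kcat = r$kcat, KM = r$KM, kcat_KM = r$kcat_KM,
                 dissipation_RT = r$dissipation_RT, X_RT = r$X_RT,
                 class_label = r$class_label,
                 stringsAsFactors = FALSE))))
  }
  stop("records must be a data frame or a list of kinetic_summary objects",
       call. = FALSE)
}

# drop rows unusable on the log scale; backward-driven cycles are excluded
# because the ensemble scaling is defined for forward-driven enzymes
filter_fit_rows <- function(df, cols) {
  keep <- rep(TRUE, nrow(df))
  reasons <- character(0)
  for (cl in cols) {
    bad <- !is.finite(df[[cl]]) | df[[cl]] <= 0
    if (any(bad & keep))
      reasons <- c(reasons, sprintf("%d row(s) with nonpositive %s", sum(bad & keep), cl))
    keep <- keep & !bad
  }
  if ("X_RT" %in% names(df)) {
    bad <- is.finite(df$X_RT) & df$X_RT < 0
    if (any(bad & keep))
      reasons <- c(reasons, sprintf("%d backward-driven row(s) (X < 0)", sum(bad & keep)))
    keep <- keep & !bad
  }
  if (length(reasons))
    warning("excluded from fit: ", paste(reasons, collapse = "; "), call. = FALSE)
  df[keep, , drop = FALSE]
}

#' Fit the dissipation power law
#'
#' Ordinary least squares of `log10(dissipation/RT)` on `log10(predictor)`,
#' where the predictor is the specificity constant `kcat/KM` or `kcat`.
#' Treating dissipation as the response follows the way the scaling is
#' stated (`diss/RT = 10^a x^b`); a reduced-major-axis mode
#' (`method = "rma"`) is exposed for sensitivity analysis since neither
#' variable is error-free. Slope standard error and the 95% CI come from
#' the t distribution with `n - 2` df.
#'
#' Rows with nonpositive values or backward drive (`X < 0`) are excluded
#' with a warning naming the reason.
#'
#' @param records data frame with columns `kcat`, `KM`, `kcat_KM`,
#'   `dissipation_RT` (and optionally `X_RT`), or a list of
#'   [catalytic_parameters()] summaries.
#' @param predictor `"kcat_over_KM"` (default) or `"kcat"`.
#' @param method `"ols"` (default) or `"rma"` (reduced major axis).
#' @return an object of class `scaling_fit`: `predictor`, `slope`,
#'   `intercept`, `slope_SE`, `intercept_SE`, `R2`, `n`, `slope_CI95`,
#'   `residuals` (log10 units), `method`.
#' @export
fit_power_law <- function(records, predictor = c("kcat_over_KM", "kcat"),
                          method = c("ols", "rma")) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  df <- records_frame(records)
  xcol <- if (predictor == "kcat_over_KM") "kcat_KM" else "kcat"
  df <- filter_fit_rows(df, c(xcol, "dissipation_RT"))
  n <- nrow(df)
  if (n < 3L) stop("power-law fit requires at least 3 usable rows", call. = FALSE)

  lx <- log10(df[[xcol]])
  ly <- log10(df$dissipation_RT)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # classical OLS standard errors, computed directly so an exact fit does
  # not trip summary.lm's perfect-fit warning
  res <- unname(stats::residuals(fit))
  s2 <- sum(res^2) / (n - 2)
  sxx <- sum((lx - mean(lx))^2)
  slope_SE <- sqrt(s2 / sxx)
  intercept_SE <- sqrt(s2 * (1 / n + mean(lx)^2 / sxx))
  R2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)

  if (method == "rma") {
    r <- stats::cor(lx, ly)
    slope <- sign(r) * stats::sd(ly) / stats::sd(lx)
    intercept <- mean(ly) - slope * mean(lx)
    # classical large-sample SE of the RMA slope
    slope_SE <- abs(slope) * sqrt((1 - r^2) / (n - 2))
  }

  tq <- stats::qt(0.975, df = n - 2)
  structure(
    list(predictor = predictor, slope = slope, intercept = intercept,
         slope_SE = slope_SE, intercept_SE = intercept_SE,
         R2 = R2, n = n,
         slope_CI95 = c(slope - tq * slope_SE, slope + tq * slope_SE),
         residuals = ly - (intercept + slope * lx),
         method = method),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit (%s): log10(diss/RT) ~ log10(%s), n = %d>\n",
              x$method, x$predictor, x$n))
  cat(sprintf("  slope b   = %.4f  (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$slope, x$slope_SE, x$slope_CI95[1], x$slope_CI95[2]))
  cat(sprintf("  intercept = %.4f  (SE %.4f)\n", x$intercept, x$intercept_SE))
  cat(sprintf("  R^2       = %.4f\n", x$R2))
  invisible(x)
}

#' Paired-bootstrap comparison of the two scaling slopes
#'
#' The slopes against `kcat` and against `kcat/KM` share the same response
#' (dissipation) on the same enzymes, so their difference cannot be tested
#' with independent-SE z statistics. Instead rows are case-resampled with
#' replacement and both slopes refit on each resample; the percentile CI of
#' `delta = b_kcat - b_kcat_over_KM` excludes zero iff the difference is
#' declared significant. Fully seeded and reproducible.
#'
#' @param records as in [fit_power_law()]; both predictors must be present.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `slope_comparison`: `delta_slope`, `CI95`,
#'   `significant`, `method`, `n_boot`, `seed`.
#' @export
compare_slopes <- function(records, n_boot = 2000L, seed) {
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  df <- records_frame(records)
  df <- filter_fit_rows(df, c("kcat", "kcat_KM", "dissipation_RT"))
  n <- nrow(df)
  if (n < 3L) stop("slope comparison requires at least 3 usable rows", call. = FALSE)

  both <- function(d) {
    lx1 <- log10(d$kcat_KM); lx2 <- log10(d$kcat); ly <- log10(d$dissipation_RT)
    c(b1 = unname(stats::coef(stats::lm(ly ~ lx1))[2]),
      b2 = unname(stats::coef(stats::lm(ly ~ lx2))[2]))
  }
  b0 <- both(df)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  deltas <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    b <- both(df[idx, , drop = FALSE])
    b["b2"] - b["b1"]
  }, numeric(1))
  ci <- unname(stats::quantile(deltas, c(0.025, 0.975), type = 7))

  structure(
    list(delta_slope = unname(b0["b2"] - b0["b1"]),
         b_kcat = unname(b0["b2"]), b_kcat_over_KM = unname(b0["b1"]),
         CI95 = ci, significant = ci[1] > 0 || ci[2] < 0,
         method = "paired-bootstrap", n_boot = as.integer(n_boot),
         seed = as.integer(seed), n = n),
    class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison (paired bootstrap, %d resamples, seed %d)>\n",
              x$n_boot, x$seed))
  cat(sprintf("  b(kcat) = %.4f, b(kcat/KM) = %.4f\n", x$b_kcat, x$b_kcat_over_KM))
  cat(sprintf("  delta = %.4f, 95%% CI [%.4f, %.4f] -> %s\n",
              x$delta_slope, x$CI95[1], x$CI95[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Fit the dissipation plane
#'
#' Least-squares plane `log10(diss/RT) = alpha log10(kcat) + beta log10(KM)
#' + gamma` in the 3D log-log-log representation. The residual standard
#' deviation is reported as the plane-thickness statistic.
#'
#' @param records as in [fit_power_law()].
#' @return an object of class `plane_fit`: `coefficients`
#'   (`alpha`, `beta`, `gamma`), `residual_SD`, `R2`, `n`.
#' @export
fit_plane <- function(records) {
  df <- records_frame(records)
  df <- filter_fit_rows(df, c("kcat", "KM", "dissipation_RT"))
  n <- nrow(df)
  if (n < 4L) stop("plane fit requires at least 4 usable rows", call. = FALSE)
  lk <- log10(df$kcat); lm_ <- log10(df$KM); ly <- log10(df$dissipation_RT)
  X <- cbind(1, lk, lm_)
  if (qr(X)$rank < 3L)
    stop("rank-deficient predictors: kcat and KM are collinear on the log scale",
         call. = FALSE)
  fit <- stats::lm(ly ~ lk + lm_)
  res <- unname(stats::residuals(fit))
  structure(
    list(coefficients = c(alpha = unname(stats::coef(fit)[2]),
                          beta = unname(stats::coef(fit)[3]),
                          gamma = unname(stats::coef(fit)[1])),
         residual_SD = sqrt(sum(res^2) / max(n - 3, 1)),
         R2 = 1 - sum(res^2) / sum((ly - mean(ly))^2), n = n),
    class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit: n = %d>\n", x$n))
  cat(sprintf("  log10(diss/RT) = %.4f log10(kcat) + %.4f log10(KM) + %.4f\n",
              x$coefficients["alpha"], x$coefficients["beta"], x$coefficients["gamma"]))
  cat(sprintf("  residual SD (thickness) = %.4f log10 units, R^2 = %.4f\n",
              x$residual_SD, x$R2))
  invisible(x)
}
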