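exact_law_frame <- function(n = 20, a = 2, b = 0.75) {
  x <- 10^seq(0, 8, length.out = n)
  data.frame(name = paste0("e", seq_len(n)),
             kcat = 10^seq(-1, 5, length.out = n),
             KM = 10^seq(-1, 5, length.out = n) / x,
             kcat_KM = x,
             dissipation_RT = 10^a * x^b,
             X_RT = 5, stringsAsFactors = FALSE)
}

test_that("a noiseless power law is recovered exactly", {
  fit <- fit_power_law(exact_law_frame(a = 2, b = 0.75))
  expect_equal(fit$slope, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_true(fit$slope_CI95[1] <= fit$slope && fit$slope <= fit$slope_CI95[2])
  # RMA mode coincides with OLS on perfectly correlated data
  expect_equal(fit_power_law(exact_law_frame(), method = "rma")$slope, 0.75,
               tolerance = 1e-12)
})

test_that("fits are invariant to row order and predictor rescaling", {
  set.seed(606)
  df <- exact_law_frame(30)
  df$dissipation_RT <- df$dissipation_RT * 10^rnorm(30, 0, 0.3)
  f0 <- fit_power_law(df)
  f1 <- fit_power_law(df[sample(30), ])
  expect_equal(f0$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f0$R2, f1$R2, tolerance = 1e-12)
  # unit rescaling of the predictor shifts only the intercept
  df2 <- df; df2$kcat_KM <- df2$kcat_KM * 1e3
  f2 <- fit_power_law(df2)
  expect_equal(f2$slope, f0$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f0$intercept - 3 * f0$slope, tolerance = 1e-8)
})

test_that("unusable rows are excluded with a reason; too few rows fail", {
  df <- exact_law_frame(6)
  df$dissipation_RT[2] <- -1
  df$X_RT[3] <- -4
  expect_warning(fit <- fit_power_law(df), "nonpositive")
  expect_equal(fit$n, 4)
  expect_error(suppressWarnings(fit_power_law(df[1:3, ])), "at least 3")
})

test_that("list-of-summary input works like the data frame route", {
  schemes <- list(toy3(),
                  cycle_scheme(c(1000, 50), c(10, 0.01),
                               substrate = list(k2nd = 1e6, conc = 1e-3)),
                  cycle_scheme(c(200, 80, 120, 30), c(5, 4, 2, 0.01),
                               substrate = list(k2nd = 2e5, conc = 1e-3)))
  recs <- lapply(schemes, catalytic_parameters)
  fit <- fit_power_law(recs)
  expect_s3_class(fit, "scaling_fit")
  expect_equal(fit$n, 3)
})

test_that("paired bootstrap of the slope difference is seeded and sane", {
  df <- exact_law_frame(25)
  # identical predictor columns -> delta exactly zero in every resample
  df_same <- df; df_same$kcat <- df_same$kcat_KM
  cmp0 <- compare_slopes(df_same, n_boot = 200, seed = 1)
  expect_equal(cmp0$delta_slope, 0, tolerance = 1e-12)
  expect_equal(unname(cmp0$CI95), c(0, 0), tolerance = 1e-12)
  expect_false(cmp0$significant)

  set.seed(999)  # global state must not leak into the seeded bootstrap
  df$dissipation_RT <- df$dissipation_RT * 10^rnorm(25, 0, 0.4)
  c1 <- compare_slopes(df, n_boot = 500, seed = 42)
  c2 <- compare_slopes(df, n_boot = 500, seed = 42)
  expect_identical(c1$CI95, c2$CI95)
  expect_error(compare_slopes(df, n_boot = 50, seed = 1), "at least 100")
  expect_error(compare_slopes(df, n_boot = 500), "seed")
})

test_that("slope-difference CI behaves under true null and true difference", {
  # null: both slopes generated equal -> CI should usually cover zero
  cover <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    lx <- runif(n, 0, 8)
    ly <- 1 + 0.8 * lx + rnorm(n, 0, 0.4)
    df <- data.frame(kcat = 10^lx, kcat_KM = 10^lx,
                     KM = 1, dissipation_RT = 10^ly, X_RT = 5)
    cmp <- compare_slopes(df, n_boot = 300, seed = s)
    if (cmp$CI95[1] <= 0 && cmp$CI95[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover, 17)  # ~95% nominal on 20 replicates

  # a real difference is detected in the majority of replicates
  detect <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 75
    lx1 <- runif(n, 0, 9)
    ldiss <- 1 + 0.72 * lx1 + rnorm(n, 0, 0.35)
    # second predictor built to carry a steeper slope against the same response
    lx2 <- (ldiss - 1 - rnorm(n, 0, 0.2)) / 0.97
    df <- data.frame(kcat = 10^lx2, kcat_KM = 10^lx1, KM = 10^(lx2 - lx1),
                     dissipation_RT = 10^ldiss, X_RT = 5)
    cmp <- compare_slopes(df, n_boot = 300, seed = s)
    if (cmp$significant) detect <- detect + 1
  }
  expect_gte(detect, 6)
})

test_that("plane fit recovers exact coefficients and flags rank deficiency", {
  n <- 30
  set.seed(707)
  lk <- runif(n, -1, 5); lm_ <- runif(n, -6, 0)
  df <- data.frame(kcat = 10^lk, KM = 10^lm_, kcat_KM = 10^(lk - lm_),
                   dissipation_RT = 10^(0.9 * lk - 0.3 * lm_ + 1.5), X_RT = 5)
  pf <- fit_plane(df)
  expect_equal(unname(pf$coefficients), c(0.9, -0.3, 1.5), tolerance = 1e-9)
  expect_equal(pf$residual_SD, 0, tolerance = 1e-9)
  expect_equal(pf$R2, 1, tolerance = 1e-12)

  # noisy data: coefficients recovered within a loose band
  df2 <- df; df2$dissipation_RT <- df2$dissipation_RT * 10^rnorm(n, 0, 0.2)
  pf2 <- fit_plane(df2)
  expect_equal(unname(pf2$coefficients["alpha"]), 0.9, tolerance = 0.3)
  expect_gt(pf2$residual_SD, 0)

  # collinear predictors on the log scale are rejected
  dfc <- df; dfc$KM <- dfc$kcat^2
  expect_error(fit_plane(dfc), "rank-deficient")
  expect_error(fit_plane(df[1:3, ]), "at least 4")
})
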