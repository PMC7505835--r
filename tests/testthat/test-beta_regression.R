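simulate_beta <- function(n, beta0, beta1, phi, seed) {
  set.seed(seed)
  x <- runif(n, 0, 10)
  mu <- plogis(beta0 + beta1 * x)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  tibble::tibble(years_since_disturbance = x,
                 y = pmin(pmax(y, 1e-12), 1 - 1e-12))
}

test_that("boundary squeeze is order-preserving and strictly interior", {
  expect_equal(squeeze_unit_interval(1, n = 100), 0.995)
  expect_equal(squeeze_unit_interval(0.5, n = 17), 0.5)
  y <- c(0, 0.2, 0.7, 1)
  ys <- squeeze_unit_interval(y, n = 50)
  expect_true(all(ys > 0 & ys < 1))
  expect_true(all(diff(ys) > 0))
  expect_error(squeeze_unit_interval(0.5, n = 1), "at least 2")
  expect_error(squeeze_unit_interval(1.2, n = 10), "0, 1")
})

test_that("beta log-likelihood matches dbeta and its known special case", {
  # mu = 0.5, phi = 2 is the uniform density: log-likelihood 0 for any y
  expect_equal(beta_loglik(c(0.1, 0.37, 0.9), 0.5, 2), 0, tolerance = 1e-12)
  y <- c(0.2, 0.5, 0.8)
  expect_equal(beta_loglik(y, 0.3, 7),
               sum(dbeta(y, 0.3 * 7, 0.7 * 7, log = TRUE)), tolerance = 1e-10)
  # density at y = mu increases with the precision
  expect_gt(beta_loglik(0.4, 0.4, 50), beta_loglik(0.4, 0.4, 5))
  expect_error(beta_loglik(c(0, 0.5), 0.5, 2), "strictly inside")
})

test_that("intercept-only fit recovers near-constant data and the ML mean", {
  y <- rep(0.62, 30)
  df <- tibble::tibble(y = y, years_since_disturbance = rep(c(1, 2, 3), 10))
  fit <- fit_beta_gam(df, "y", df_smooth = 1L)
  ys <- squeeze_unit_interval(y, n = length(y))
  expect_equal(mean(fit$fitted), mean(ys), tolerance = 1e-4)
})

test_that("slope and precision are recovered on simulated beta data", {
  df <- simulate_beta(400, beta0 = -0.5, beta1 = 0.2, phi = 20, seed = 42)
  fit <- fit_beta_gam(df, "y", df_smooth = 4L)
  expect_equal(fit$edf, 1L)  # linear truth, AIC should pick the linear term
  est <- tidy(fit)
  slope <- dplyr::filter(est, term == "years_since_disturbance")
  expect_lt(abs(slope$estimate - 0.2), 3 * slope$std.error)
  expect_equal(fit$phi, 20, tolerance = 0.35)
  expect_lt(fit$p_value, 1e-6)
  expect_gt(fit$pseudo_r2, 0.3)
})

test_that("the fit agrees with an independent penalized-likelihood fit", {
  skip_if_not_installed("mgcv")
  df <- simulate_beta(150, beta0 = 0.3, beta1 = -0.15, phi = 12, seed = 7)
  fit <- fit_beta_gam(df, "y", df_smooth = 1L)
  ys <- squeeze_unit_interval(df$y, n = nrow(df))
  g <- mgcv::gam(ys ~ years_since_disturbance, family = mgcv::betar(),
                 data = df, method = "ML")
  expect_equal(unname(fit$coefficients),
               unname(stats::coef(g)), tolerance = 1e-3)
  expect_equal(fit$fitted, unname(stats::fitted(g)), tolerance = 1e-3)
})

test_that("categorical covariates enter as fixed effects; aliasing is an error", {
  df <- simulate_beta(120, beta0 = 0, beta1 = 0.1, phi = 15, seed = 3)
  df$taxon_group <- rep(c("beetles", "fungi", "plants"), 40)
  df$copy <- df$taxon_group  # perfectly aliased covariate
  fit <- fit_beta_gam(df, "y", covariates = "taxon_group", df_smooth = 2L)
  expect_true(any(grepl("taxon_group", names(fit$coefficients))))
  expect_error(
    fit_beta_gam(df, "y", covariates = c("taxon_group", "copy")),
    "rank deficient")

  # permuting category labels leaves fitted values unchanged
  df2 <- df
  relabel <- c(beetles = "zz", fungi = "aa", plants = "mm")
  df2$taxon_group <- unname(relabel[df$taxon_group])
  fit2 <- fit_beta_gam(df2, "y", covariates = "taxon_group", df_smooth = 2L)
  expect_equal(fit$fitted, fit2$fitted, tolerance = 1e-6)
})

test_that("the optimizer never ends below its starting log-likelihood", {
  for (seed in 1:5) {
    df <- simulate_beta(60, beta0 = 0.2, beta1 = 0.05, phi = 8, seed = seed)
    fit <- fit_beta_gam(df, "y", df_smooth = 3L)
    ys <- squeeze_unit_interval(df$y, n = nrow(df))
    # the start is the logit-least-squares fit; final ML must not be worse
    eta0 <- qlogis(pmin(pmax(ys, 1e-4), 1 - 1e-4))
    start_ll <- beta_loglik(ys, plogis(stats::fitted(lm(eta0 ~ 1))), 2)
    expect_gte(fit$loglik, start_ll)
    expect_true(is.finite(fit$loglik))
    expect_gt(fit$phi, 0)
    expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  }
})

test_that("AIC selects the linear term on linear-truth data most of the time", {
  # the selection probability is ~0.8 under these conditions; allow two
  # binomial standard errors (0.08 at 100 replicates) of sampling slack
  picks <- vapply(1:100, function(seed) {
    df <- simulate_beta(200, beta0 = -0.3, beta1 = 0.15, phi = 20, seed = seed)
    fit_beta_gam(df, "y", df_smooth = 4L)$edf
  }, numeric(1))
  expect_gte(mean(picks == 1), 0.72)
})
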