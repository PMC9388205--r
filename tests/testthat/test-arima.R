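test_that("log-likelihood reduces to closed forms without ARMA structure", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  pair <- series_pair(weekly_series(2 * x, ANCHOR, "y"),
                      weekly_series(x, ANCHOR, "x"))
  spec <- transfer_model_spec(noise = noise_spec(integer(0)))
  # zero residuals, unit variance: -(T/2) log(2*pi)
  ll <- model_loglik(list(reg = c(0, 2), phi = numeric(0), theta = numeric(0),
                          sigma2 = 1), pair, spec)
  expect_equal(ll, -length(x) / 2 * log(2 * pi), tolerance = 1e-12)

  # equals the OLS Gaussian log-likelihood at the OLS solution
  gp <- gen_pair(default_cfg(), seed = 31)
  y <- gp$pair$dependent$counts; xc <- gp$pair$control$counts
  ols <- lm(y ~ xc)
  s2 <- mean(residuals(ols)^2)
  ll_ols <- model_loglik(list(reg = unname(coef(ols)), phi = numeric(0),
                              theta = numeric(0), sigma2 = s2),
                         gp$pair, transfer_model_spec(noise = noise_spec(integer(0))))
  expect_equal(ll_ols, as.numeric(logLik(ols)), tolerance = 1e-9)

  expect_error(model_loglik(list(reg = c(0, 2), sigma2 = -1), pair, spec),
               "positive")
  expect_error(model_loglik(list(reg = c(NA, 2), sigma2 = 1), pair, spec),
               "non-finite")
})

test_that("fitted parameters maximize the likelihood", {
  gp <- gen_pair(default_cfg(), seed = 8)
  spec <- default_spec()
  fit <- fit_transfer_model(gp$pair, spec)
  at <- function(reg, phi, s2)
    model_loglik(list(reg = reg, phi = phi, theta = numeric(0), sigma2 = s2),
                 gp$pair, spec)
  reg_hat <- unname(fit$coef[1:3]); phi_hat <- unname(fit$phi)
  ll_hat <- at(reg_hat, phi_hat, fit$sigma2)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-8)
  # perturbing any single parameter lowers the likelihood
  for (j in 1:3) {
    bump <- reg_hat; bump[j] <- bump[j] + 0.5
    expect_lt(at(bump, phi_hat, fit$sigma2), ll_hat)
  }
  expect_lt(at(reg_hat, phi_hat + c(0.05, 0), fit$sigma2), ll_hat)
  expect_lt(at(reg_hat, phi_hat, fit$sigma2 * 1.2), ll_hat)
})

test_that("an exact linear relation is recovered with zero residuals", {
  x <- c(10, 20, 15, 30, 25, 40, 35, 50)
  pair <- series_pair(weekly_series(2 * x, ANCHOR, "y"),
                      weekly_series(x, ANCHOR, "x"))
  fit <- fit_transfer_model(pair,
                            transfer_model_spec(noise = noise_spec(integer(0)),
                                                burn_in_weeks = 0L))
  expect_equal(unname(fit$beta_control), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coef["(Intercept)"]), 0, tolerance = 1e-8)
  expect_true(all(abs(fit$residuals) < 1e-8))
})

test_that("with ARMA terms disabled the fit equals closed-form least squares", {
  gp <- gen_pair(default_cfg(), seed = 12)
  ind <- default_indicator()
  spec <- transfer_model_spec(noise = noise_spec(integer(0)), intervention = ind)
  fit <- fit_transfer_model(gp$pair, spec)
  y <- gp$pair$dependent$counts
  X <- cbind(1, gp$pair$control$counts, ind)
  b <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% b)^2)
  se <- sqrt(diag(rss / length(y) * solve(crossprod(X))))  # Gaussian-ML variance
  expect_equal(unname(fit$coef), unname(drop(b)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(se), tolerance = 1e-6)
})

test_that("exact likelihood agrees with an independent state-space ARIMA fit", {
  gp <- gen_pair(default_cfg(), seed = 42)
  ind <- default_indicator()
  spec <- transfer_model_spec(noise = noise_spec(c(1, 5)), intervention = ind)
  fit <- fit_transfer_model(gp$pair, spec)
  orc <- stats::arima(gp$pair$dependent$counts, order = c(5, 0, 0),
                      xreg = cbind(control = gp$pair$control$counts,
                                   intervention = ind),
                      fixed = c(NA, 0, 0, 0, NA, NA, NA, NA),
                      transform.pars = FALSE, method = "ML")
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$phi), unname(coef(orc)[c("ar1", "ar5")]), tolerance = 1e-3)
  expect_equal(unname(fit$beta_control), unname(coef(orc)["control"]), tolerance = 1e-4)
  expect_equal(unname(fit$omega_intervention), unname(coef(orc)["intervention"]),
               tolerance = 1e-3)
  se_orc <- sqrt(diag(orc$var.coef))
  expect_equal(unname(fit$se["AR(1)"]), unname(se_orc["ar1"]), tolerance = 1e-3)
  expect_equal(unname(fit$se["intervention"]), unname(se_orc["intervention"]),
               tolerance = 1e-2)
})

test_that("conditional and exact likelihood methods agree on the default fixture", {
  gp <- gen_pair(default_cfg(), seed = 42)
  spec <- default_spec()
  fe <- fit_transfer_model(gp$pair, spec, method = "exact")
  fc <- fit_transfer_model(gp$pair, spec, method = "css")
  expect_lt(abs(fe$beta_control - fc$beta_control), 5e-3)
  expect_lt(max(abs(fe$phi - fc$phi)), 0.01)
  # count-scale coefficients agree well within a small fraction of their SEs
  expect_lt(abs(fe$omega_intervention - fc$omega_intervention),
            0.05 * fe$se["intervention"])
})

test_that("a synthetic fit recovers the generator truth within its intervals", {
  cfg <- default_cfg()
  gp <- gen_pair(cfg, seed = 101)
  fit <- fit_transfer_model(gp$pair, default_spec(cfg))
  tr <- gp$truth
  expect_true(fit$ci95["control", 1] <= tr$beta_control &&
              tr$beta_control <= fit$ci95["control", 2])
  expect_true(fit$ci95["intervention", 1] <= tr$omega &&
              tr$omega <= fit$ci95["intervention", 2])
  # structural sanity
  expect_gt(fit$sigma2, 0)
  expect_equal(unname(fit$ci95[, 2] - fit$coef), unname(fit$coef - fit$ci95[, 1]),
               tolerance = 1e-10)  # symmetric intervals
  expect_length(fit$residuals, 142 - 6)
  expect_lt(abs(mean(fit$residuals)), 3 * sd(fit$residuals) / sqrt(length(fit$residuals)))
})

test_that("differencing and short-series guards behave", {
  gp <- gen_pair(default_cfg(), seed = 3)
  spec_d <- transfer_model_spec(noise = noise_spec(c(1), d = 1L))
  fit_d <- fit_transfer_model(gp$pair, spec_d)
  expect_identical(fit_d$n, 141L)   # one observation lost to differencing
  short <- series_pair(weekly_series(1:6 + 10, ANCHOR), weekly_series(1:6, ANCHOR))
  expect_error(fit_transfer_model(short,
                                  transfer_model_spec(noise = noise_spec(c(1, 5)))),
               "too short")
})
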