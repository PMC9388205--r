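test_that("outlier regressor patterns are correct", {
  expect_identical(outlier_regressor("LS", 3, series_length = 5), c(0, 0, 1, 1, 1))
  expect_equal(outlier_regressor("TC", 3, 0.7, 5), c(0, 0, 1, 0.7, 0.49))
  for (Tn in c(1, 10, 142))
    expect_identical(sum(outlier_regressor("AO", max(1, Tn - 1), series_length = Tn)), 1)
  expect_error(outlier_regressor("IO", 3, series_length = 5), "unknown outlier type")
  expect_error(outlier_regressor("AO", 9, series_length = 5))
})

test_that("under white noise the AO statistic is the standardized residual", {
  set.seed(21)
  noise <- rnorm(60)
  pair <- series_pair(weekly_series(100 + noise - mean(noise), ANCHOR),
                      weekly_series(rep(50, 60), ANCHOR))
  spec <- transfer_model_spec(noise = noise_spec(integer(0)),
                              include_control = FALSE, burn_in_weeks = 0L)
  fit <- fit_transfer_model(pair, spec)
  cfgo <- outlier_config(robust_sigma = FALSE)
  st <- scan_t_stats(fit, pair, spec, cfgo)
  ao <- st[st$type == "AO", ]
  r <- pair$dependent$counts - fit$fitted
  # df-corrected scale: ML sigma2 * n/(n - 1 fitted coefficient)
  sigma <- sqrt(fit$sigma2 * fit$n / (fit$n - 1))
  expect_equal(ao$t_stat[match(1:60, ao$week)], r / sigma, tolerance = 1e-10)

  flat <- series_pair(weekly_series(rep(100, 60), ANCHOR),
                      weekly_series(rep(50, 60), ANCHOR))
  flat_fit <- fit_transfer_model(flat, spec)
  expect_error(scan_t_stats(flat_fit, flat, spec, cfgo), "degenerate")
})

test_that("candidates collinear with the design are screened out", {
  gp <- gen_pair(default_cfg(), seed = 14)
  spec <- transfer_model_spec(noise = noise_spec(integer(0)))
  fit <- fit_transfer_model(gp$pair, spec)
  st <- scan_t_stats(fit, gp$pair, spec, outlier_config())
  # a level shift at week 1 duplicates the intercept column
  expect_false(any(st$type == "LS" & st$week == 1))
})

test_that("an injected level shift dominates the scan at its true week", {
  cfg <- synthetic_config(omega = 0,
                          injected_outliers = list(list(type = "LS", week = 60,
                                                        magnitude = -300)))
  gp <- gen_pair(cfg, seed = 6)
  spec <- transfer_model_spec(noise = noise_spec(c(1, 5)), intervention = NULL)
  da <- suppressWarnings(detect_and_adjust(gp$pair, spec))
  st <- scan_t_stats(da$initial_fit, gp$pair, spec, outlier_config())
  top <- st[which.max(abs(st$t_stat)), ]
  expect_identical(top$type, "LS")
  expect_identical(top$week, 60L)
  expect_identical(da$outliers$type[1], "LS")
  expect_identical(da$outliers$week[1], 60L)
})

test_that("detection recovers an injected TC/LS pair and adjusts jointly", {
  cfg <- synthetic_config(
    omega = 0,
    injected_outliers = list(list(type = "TC", week = 81, magnitude = 240),
                             list(type = "LS", week = 124, magnitude = -300)))
  spec <- transfer_model_spec(noise = noise_spec(c(1, 5)), intervention = NULL)
  hits <- sapply(1:10, function(s) {
    gp <- gen_pair(cfg, seed = s)
    da <- suppressWarnings(detect_and_adjust(gp$pair, spec))
    # every accepted outlier strictly increases the maximized log-likelihood
    expect_true(all(diff(da$loglik_path) > 0))
    all(c("TC 81", "LS 124") %in% paste(da$outliers$type, da$outliers$week))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("rescanning an adjusted model finds nothing new (idempotence)", {
  cfg <- synthetic_config(omega = 0,
                          injected_outliers = list(list(type = "LS", week = 124,
                                                        magnitude = -300)))
  gp <- gen_pair(cfg, seed = 2)
  spec <- transfer_model_spec(noise = noise_spec(c(1, 5)), intervention = NULL)
  da <- suppressWarnings(detect_and_adjust(gp$pair, spec))
  expect_gt(nrow(da$outliers), 0)
  xr <- sapply(seq_len(nrow(da$outliers)), function(i)
    outlier_regressor(da$outliers$type[i], da$outliers$week[i], 0.7, 142))
  colnames(xr) <- paste0(da$outliers$type, "_", da$outliers$week)
  da2 <- suppressWarnings(detect_and_adjust(gp$pair, spec, xreg = xr))
  expect_identical(nrow(da2$outliers), 0L)
})

test_that("outlier adjustment narrows the intervention interval when outliers exist", {
  cfg <- synthetic_config(
    injected_outliers = list(list(type = "TC", week = 81, magnitude = 240),
                             list(type = "LS", week = 124, magnitude = -300)))
  spec <- default_spec(cfg)
  shrunk <- sapply(c(3, 7, 10, 13, 23), function(s) {
    gp <- gen_pair(cfg, seed = s)
    da <- suppressWarnings(detect_and_adjust(gp$pair, spec))
    w0 <- diff(da$initial_fit$ci95["intervention", ])
    w1 <- diff(da$fit$ci95["intervention", ])
    w1 < w0
  })
  expect_gte(mean(shrunk), 0.6)  # majority property
})

test_that("outlier table serializes with week start dates", {
  out <- data.frame(iteration = 1:2, type = c("TC", "LS"), week = c(81L, 124L),
                    magnitude = c(240.1, -301.5), t_stat = c(5.2, -12.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outliers_csv(out, ANCHOR, path)
  back <- utils::read.csv(path)
  expect_identical(back$week_start_date, c("2019-07-19", "2020-05-15"))
  expect_identical(back$week_index, c(81L, 124L))
})
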