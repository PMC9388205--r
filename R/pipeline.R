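#' Pipeline configuration
#'
#' Bundles every analysis choice: inclusion filter, study span, intervention
#' coding, noise model, outlier scan settings, effect-translation durations
#' and the RNG seed.
#'
#' @param filter a [filter_spec()]
#' @param anchor_date Friday opening week 1
#' @param end_date Thursday closing the final week
#' @param intervention an [intervention_spec()]; built for the span if `NULL`
#' @param noise a [noise_spec()]
#' @param outliers an [outlier_config()], or `NULL` to disable the scan
#' @param effect_durations exposed-week durations reported in effect
#'   summaries (both the coded window and the narrower convention)
#' @param burn_in_weeks initial weeks dropped from residual reporting
#' @param method likelihood method passed to the fitters
#' @param seed RNG seed for any stochastic stage
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(filter = filter_spec(),
                            anchor_date = "2018-01-05",
                            end_date = "2020-09-24",
                            intervention = NULL,
                            noise = noise_spec(),
                            outliers = outlier_config(),
                            effect_durations = c(8L, 9L),
                            burn_in_weeks = 6L,
                            method = "exact",
                            seed = 1L) {
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  end_date <- as_date_strict(end_date, "end_date")
  n_weeks <- span_weeks(anchor_date, end_date)
  if (is.null(intervention))
    intervention <- intervention_spec("pulse", "2020-03-13", 9L, n_weeks)
  if (intervention$series_length != n_weeks)
    stop("intervention series_length differs from the configured span")
  structure(list(filter = filter, anchor_date = anchor_date,
                 end_date = end_date, n_weeks = n_weeks,
                 intervention = intervention, noise = noise,
                 outliers = outliers,
                 effect_durations = as.integer(effect_durations),
                 burn_in_weeks = as.integer(burn_in_weeks),
                 method = method, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# records -> series pair under a config (split by payer)
records_to_pair <- function(records, config) {
  kept <- filter_encounters(records, config$filter)
  dep <- bin_weekly(kept[kept$payer == "restricted_medical", , drop = FALSE],
                    config$anchor_date, config$n_weeks, "undocumented (restricted payer)")
  ctl <- bin_weekly(kept[kept$payer == "full_medical", , drop = FALSE],
                    config$anchor_date, config$n_weeks, "full-scope payer control")
  series_pair(dep, ctl)
}

#' Run the five-step interrupted time-series analysis
#'
#' (1) regress the dependent on the control series; (2) identify residual
#' autocorrelation and confirm (or override with) the configured subset-AR
#' noise model; (3) re-estimate with the intervention indicator added;
#' (4) Ljung-Box residual check, surfacing failure as a warning; (5) when an
#' outlier configuration is present, iteratively detect and jointly adjust
#' for AO/TC/LS outliers. Effect summaries are translated from the final
#' intervention coefficient at each configured duration.
#'
#' @param input a [series_pair()] or an encounter-record data.frame
#' @param config a [pipeline_config()]
#' @return an `its_report`
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pair <- .stage("ingest", {
    if (inherits(input, "series_pair")) input
    else records_to_pair(input, config)
  })
  if (length(pair$dependent$counts) != config$n_weeks)
    stop("pipeline stage 'ingest' failed: series length != configured span")

  # (1) regression-only transfer function
  spec0 <- transfer_model_spec(noise = noise_spec(integer(0)),
                               include_control = TRUE, intervention = NULL,
                               burn_in_weeks = config$burn_in_weeks)
  fit_reg <- .stage("regression", fit_transfer_model(pair, spec0, method = config$method))

  # (2) noise identification on its residuals (advisory)
  suggested <- .stage("identification", identify_noise(unname(fit_reg$residuals)))
  noise_used <- config$noise
  identification_agrees <- identical(suggested$ar_lags, config$noise$ar_lags)
  if (!identification_agrees)
    message("noise identification suggests AR lags {",
            paste(suggested$ar_lags, collapse = ","),
            "}; using configured {", paste(config$noise$ar_lags, collapse = ","), "}")

  # (3) intervention-augmented model
  ind <- .stage("intervention", make_indicator(config$intervention, config$anchor_date))
  spec <- transfer_model_spec(noise = noise_used, include_control = TRUE,
                              intervention = ind,
                              burn_in_weeks = config$burn_in_weeks)
  fit_init <- .stage("estimation", fit_transfer_model(pair, spec, method = config$method))

  # (4) residual autocorrelation check
  lb <- .stage("diagnostics", ljung_box(unname(fit_init$residuals), n_lags = 12L,
                                        n_fitted = fit_init$n_free_arma))
  if (lb$p_value < 0.05)
    warning(sprintf("residual autocorrelation flagged (Ljung-Box p = %.4f)", lb$p_value))

  # (5) outlier detection and joint adjustment
  scan <- NULL
  fit_final <- fit_init
  lb_adj <- NULL
  if (!is.null(config$outliers)) {
    scan <- .stage("outlier_scan",
                   detect_and_adjust(pair, spec, config$outliers,
                                     method = config$method,
                                     initial_fit = fit_init))
    fit_final <- scan$fit
    lb_adj <- ljung_box(unname(fit_final$residuals), n_lags = 12L,
                        n_fitted = fit_final$n_free_arma)
  }

  weekly_mean <- mean(pair$dependent$counts)
  omega <- fit_final$omega_intervention
  effects <- lapply(config$effect_durations, function(dur)
    effect_summary(omega, dur, weekly_mean))
  names(effects) <- paste0("weeks_", config$effect_durations)
  mag_change <- if (!is.null(scan) && nrow(scan$outliers) > 0)
    magnitude_change(fit_init$omega_intervention, omega) else NULL

  # outliers detected inside the intervention window compete with omega
  flagged_in_window <- if (!is.null(scan) && nrow(scan$outliers) > 0)
    scan$outliers$week[ind[scan$outliers$week] == 1] else integer(0)

  structure(list(pair = pair, config = config,
                 initial_fit = fit_init,
                 adjusted_fit = if (!is.null(scan)) scan$fit else NULL,
                 outliers = if (!is.null(scan)) scan$outliers else NULL,
                 outliers_in_window = flagged_in_window,
                 regression_fit = fit_reg,
                 suggested_noise = suggested,
                 identification_agrees = identification_agrees,
                 ljung_box = lb,
                 ljung_box_adjusted = lb_adj,
                 weekly_mean = weekly_mean,
                 effects = effects,
                 magnitude_change_pct = mag_change,
                 residuals = fit_final$residuals,
                 variant = "primary"),
            class = "its_report")
}

#' @export
print.its_report <- function(x, ...) {
  cat("Interrupted time-series report (", x$variant, " analysis)\n", sep = "")
  cat(sprintf("  span: %d weeks from %s; weekly mean %.2f (dependent)\n",
              length(x$pair$dependent$counts), format(x$pair$dependent$anchor_date),
              x$weekly_mean))
  cat("\nInitial model:\n"); print(x$initial_fit)
  if (!is.null(x$adjusted_fit)) {
    cat("\nOutlier-adjusted model:\n"); print(x$adjusted_fit)
    if (nrow(x$outliers) > 0) {
      cat("\nDetected outliers:\n"); print(x$outliers)
      cat(sprintf("\nIntervention magnitude change after adjustment: %.1f%%\n",
                  x$magnitude_change_pct))
    } else cat("\nNo outliers detected.\n")
  }
  cat(sprintf("\nLjung-Box (12 lags), initial model: Q = %.2f, p = %.4f\n",
              x$ljung_box$stat, x$ljung_box$p_value))
  if (!is.null(x$ljung_box_adjusted))
    cat(sprintf("Ljung-Box (12 lags), adjusted model: Q = %.2f, p = %.4f\n",
                x$ljung_box_adjusted$stat, x$ljung_box_adjusted$p_value))
  cat("\nEffect translation:\n")
  for (nm in names(x$effects)) { cat("  "); print(x$effects[[nm]]) }
  invisible(x)
}

#' Serialize an analysis report to JSON
#' @param report an `its_report`
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  fit_block <- function(f) if (is.null(f)) NULL else list(
    coef = as.list(f$coef), se = as.list(f$se),
    ci95 = apply(f$ci95, 1, function(r) list(lower = r[[1]], upper = r[[2]])),
    p_value = as.list(f$p_value), sigma2 = f$sigma2, loglik = f$loglik)
  out <- list(schema_version = "1.0",
              variant = report$variant,
              n_weeks = length(report$pair$dependent$counts),
              weekly_mean_dependent = report$weekly_mean,
              initial_model = fit_block(report$initial_fit),
              outlier_adjusted_model = fit_block(report$adjusted_fit),
              outliers = report$outliers,
              ljung_box = report$ljung_box,
              ljung_box_adjusted = report$ljung_box_adjusted,
              effects = lapply(report$effects, unclass),
              magnitude_change_pct = report$magnitude_change_pct)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Plot the observed and residual series
#'
#' Two panels: observed dependent counts, and model residuals (burn-in weeks
#' excluded), with the intervention window marked by dashed vertical lines
#' and each January marked by a solid line.
#'
#' @param x an `its_report`
#' @param ... unused
#' @export
plot.its_report <- function(x, ...) {
  starts <- week_starts(x$pair$dependent)
  ind <- x$config$intervention
  w0 <- week_index_of(ind$start_date, x$config$anchor_date)
  w1 <- if (ind$kind == "pulse") w0 + ind$n_weeks - 1L else length(starts)
  jan <- which(format(starts, "%m") == "01" & !duplicated(format(starts, "%Y")))
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(starts, x$pair$dependent$counts, type = "l",
                 ylab = "weekly count", xlab = "", main = "Observed dependent series")
  graphics::abline(v = starts[jan], col = "grey60")
  graphics::abline(v = starts[c(w0, w1)], lty = 2)
  res <- x$residuals
  graphics::plot(starts[as.integer(names(res))], res, type = "l",
                 ylab = "residual", xlab = "", main = "Model residuals")
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(v = starts[c(w0, w1)], lty = 2)
  invisible(x)
}
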