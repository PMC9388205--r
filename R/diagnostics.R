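#' Residual autocorrelation diagnostics
#'
#' Sample ACF and PACF with the Bartlett \eqn{\pm 1.96/\sqrt{T}} reference
#' band, for Box-Jenkins identification of residual structure.
#'
#' @param x numeric series
#' @param max_lag largest lag examined
#' @return a `diagnostics_report`: `acf` (lags 0..max_lag), `pacf`
#'   (lags 1..max_lag), `bartlett_band`, `flagged_lags` (lags whose ACF
#'   exceeds the band)
#' @export
acf_pacf <- function(x, max_lag = 20L) {
  max_lag <- as.integer(max_lag)
  stopifnot(length(x) > max_lag + 1)
  if (stats::sd(x) == 0) stop("constant series: autocorrelation undefined")
  a <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)
  p <- drop(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
  band <- 1.96 / sqrt(length(x))
  structure(list(
    acf = stats::setNames(a, 0:max_lag),
    pacf = stats::setNames(p, 1:max_lag),
    bartlett_band = band,
    flagged_lags = which(abs(a[-1]) > band)
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("ACF/PACF over %d lags, Bartlett band +/- %.4f\n",
              length(x$pacf), x$bartlett_band))
  cat("flagged ACF lags:",
      if (length(x$flagged_lags)) paste(x$flagged_lags, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' @param residuals numeric residual series
#' @param n_lags number of lags pooled into the statistic
#' @param n_fitted number of ARMA parameters estimated (degrees-of-freedom
#'   correction)
#' @return list with `stat`, `p_value`, `df`
#' @export
ljung_box <- function(residuals, n_lags = 12L, n_fitted = 0L) {
  n_lags <- as.integer(n_lags); n_fitted <- as.integer(n_fitted)
  if (n_lags <= n_fitted) stop("n_lags must exceed n_fitted")
  stopifnot(length(residuals) > n_lags)
  if (stats::sd(residuals) == 0) stop("degenerate residuals (zero variance)")
  bt <- stats::Box.test(residuals, lag = n_lags, type = "Ljung-Box", fitdf = n_fitted)
  list(stat = unname(bt$statistic), p_value = unname(bt$p.value),
       df = unname(bt$parameter))
}

#' Suggest a subset-AR noise model from regression residuals
#'
#' Flags the lags whose partial autocorrelation exceeds the Bartlett band;
#' the flagged set is a suggested subset-AR specification. Advisory only —
#' the pipeline configuration decides the final noise model, as Box-Jenkins
#' identification is analyst-guided.
#'
#' @param residuals residuals of the regression-only model
#' @param max_lag largest candidate lag
#' @return a [noise_spec()] with `ar_lags` set to the flagged lags (possibly
#'   empty)
#' @export
identify_noise <- function(residuals, max_lag = 10L) {
  rep <- acf_pacf(residuals, max_lag = max_lag)
  lags <- which(abs(rep$pacf) > rep$bartlett_band)
  noise_spec(ar_lags = as.integer(lags), ma_lags = integer(0), d = 0L)
}
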