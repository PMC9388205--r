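#' Intervention indicator specification
#'
#' A pulse is coded 1 for `n_weeks` consecutive weeks starting at
#' `start_date`'s week and 0 elsewhere; a step is coded 1 from that week to
#' the end of the series (a sustained "switch").
#'
#' @param kind `"pulse"` or `"step"`
#' @param start_date Friday opening the first exposed week
#' @param n_weeks pulse duration in weeks (ignored for steps)
#' @param series_length total number of weeks T
#' @return an `intervention_spec`
#' @export
intervention_spec <- function(kind = c("pulse", "step"), start_date,
                              n_weeks = 9L, series_length) {
  kind <- match.arg(kind)
  start_date <- as_date_strict(start_date, "start_date")
  n_weeks <- as.integer(n_weeks)
  series_length <- as.integer(series_length)
  stopifnot(n_weeks >= 0, series_length >= 1)
  structure(list(kind = kind, start_date = start_date, n_weeks = n_weeks,
                 series_length = series_length),
            class = "intervention_spec")
}

#' Build the binary intervention indicator
#'
#' @param spec an [intervention_spec()]
#' @param anchor_date the Friday opening week 1 of the series
#' @return 0/1 vector of length `series_length`
#' @export
make_indicator <- function(spec, anchor_date) {
  stopifnot(inherits(spec, "intervention_spec"))
  Tn <- spec$series_length
  ind <- numeric(Tn)
  if (spec$kind == "pulse" && spec$n_weeks == 0L) return(ind)
  w0 <- week_index_of(spec$start_date, anchor_date)
  if (w0 > Tn) stop("intervention starts after the series ends")
  if (spec$kind == "pulse") {
    w1 <- w0 + spec$n_weeks - 1L
    if (w1 > Tn) stop("pulse window extends past the series end")
    ind[w0:w1] <- 1
  } else {
    ind[w0:Tn] <- 1
  }
  ind
}

#' Translate an intervention coefficient into effect summaries
#'
#' For a weekly-count model, a coefficient \eqn{\omega} on the intervention
#' indicator translates to \eqn{|\omega| \times} duration events avoided over
#' the exposed window, and \eqn{100\,|\omega| / \bar{y}} percent below the
#' expected weekly level.
#'
#' @param omega fitted intervention coefficient (counts per week)
#' @param duration_weeks number of exposed weeks used for the translation
#' @param weekly_mean mean weekly count of the dependent series
#' @return an `effect_summary`: `avoided_visits`, `pct_below_expected`,
#'   plus display-rounded versions
#' @export
effect_summary <- function(omega, duration_weeks, weekly_mean) {
  stopifnot(duration_weeks >= 0)
  if (weekly_mean <= 0) stop("weekly_mean must be positive")
  avoided <- abs(omega) * duration_weeks
  pct <- 100 * abs(omega) / weekly_mean
  structure(list(avoided_visits = avoided,
                 pct_below_expected = pct,
                 duration_weeks = as.integer(duration_weeks),
                 weekly_mean = weekly_mean,
                 avoided_visits_rounded = round(avoided),
                 pct_below_expected_rounded = round(pct, 2)),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("Over %d exposed weeks: %.2f events avoided (~%d), %.2f%% below expected weekly levels\n",
              x$duration_weeks, x$avoided_visits, x$avoided_visits_rounded,
              x$pct_below_expected))
  invisible(x)
}

#' Percent change in coefficient magnitude
#'
#' How much an adjustment (e.g. outlier correction) changed the size of a
#' point estimate: \eqn{100(|\omega_{adj}| - |\omega_0|)/|\omega_0|}.
#'
#' @param initial_omega,adjusted_omega coefficients before/after adjustment
#' @return percent change in magnitude (positive = grew)
#' @export
magnitude_change <- function(initial_omega, adjusted_omega) {
  if (initial_omega == 0) stop("initial coefficient is zero")
  100 * (abs(adjusted_omega) - abs(initial_omega)) / abs(initial_omega)
}
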