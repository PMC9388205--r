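#' Synthetic weekly ED-count study configuration
#'
#' Defines the generating process for a pair of aligned weekly count series
#' that mimics the study design the package analyses: a control series with
#' a sustained pandemic-era level drop, and a dependent series that follows
#' the control contemporaneously, carries subset-AR noise, dips further
#' during a coded intervention window, and may contain injected outliers.
#' Defaults are calibrated to the study conditions (142 Friday-anchored
#' weeks from 2018-01-05; weekly means 544.25 / 571.08 with SDs 107.19 /
#' 91.14; control coefficient 0.97; AR coefficients 0.09 at lag 1 and 0.06
#' at lag 5; intervention pulse of 9 weeks from 2020-03-13 with effect
#' -54.33 counts/week).
#'
#' @param n_weeks series length T
#' @param anchor_date Friday opening week 1
#' @param control_mean,control_sd pre-drop level and week-to-week SD of the
#'   control series
#' @param dependent_mean_target pre-intervention expected mean of the
#'   dependent series; sets the regression intercept
#' @param dependent_sd_target reported SD of the dependent series (emergent,
#'   checked, not enforced)
#' @param beta_control contemporaneous control coefficient
#' @param phi named numeric map lag -> AR coefficient (subset AR)
#' @param omega intervention effect in counts per week
#' @param intervention an [intervention_spec()]
#' @param shared_covid_drop fractional sustained drop in the control level
#'   from the intervention start onward (a free parameter of the generator,
#'   not an estimate)
#' @param seasonal_amplitude amplitude of an annual (52-week) sinusoid added
#'   to the control level
#' @param innovation_sd SD of the dependent series' AR innovations; the
#'   default 60 makes the dependent SD emerge near its target given
#'   `beta_control` and `control_sd`
#' @param injected_outliers list of `list(type=, week=, magnitude=)` entries
#'   added to the dependent series
#' @param decoy_fraction fraction of extra encounter records that fail the
#'   inclusion filters (exercises ingestion)
#' @return a `synthetic_config`
#' @export
synthetic_config <- function(n_weeks = 142L, anchor_date = "2018-01-05",
                             control_mean = 571.08, control_sd = 91.14,
                             dependent_mean_target = 544.25,
                             dependent_sd_target = 107.19,
                             beta_control = 0.97,
                             phi = c("1" = 0.09, "5" = 0.06),
                             omega = -54.33,
                             intervention = intervention_spec(
                               "pulse", "2020-03-13", 9L, n_weeks),
                             shared_covid_drop = 0.35,
                             seasonal_amplitude = 0,
                             innovation_sd = 60,
                             injected_outliers = list(),
                             decoy_fraction = 0.1) {
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  stopifnot(control_sd > 0, innovation_sd > 0, control_mean > 0,
            dependent_mean_target > 0, shared_covid_drop >= 0,
            shared_covid_drop < 1, decoy_fraction >= 0, decoy_fraction < 1)
  lags <- as.integer(names(phi))
  if (length(phi) && (any(is.na(lags)) || any(lags < 1)))
    stop("phi must be named by positive integer lags")
  phi_full <- .expand_lags(unname(phi), lags, if (length(lags)) max(lags) else 0L)
  if (!ar_stationary(phi_full)) stop("phi implies a non-stationary AR model")
  structure(list(n_weeks = as.integer(n_weeks), anchor_date = anchor_date,
                 control_mean = control_mean, control_sd = control_sd,
                 dependent_mean_target = dependent_mean_target,
                 dependent_sd_target = dependent_sd_target,
                 beta_control = beta_control, phi = phi, omega = omega,
                 intervention = intervention,
                 shared_covid_drop = shared_covid_drop,
                 seasonal_amplitude = seasonal_amplitude,
                 innovation_sd = innovation_sd,
                 injected_outliers = injected_outliers,
                 decoy_fraction = decoy_fraction),
            class = "synthetic_config")
}

# deterministic per-stage seed derivation, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  offs <- c(control = 11L, noise = 23L, encounters = 37L, decoys = 53L)
  (as.integer(seed) %% 1000000L) * 1913L + offs[[stage]]
}

#' Generate the control weekly series
#'
#' Control counts are `round(max(0, level_t + seasonal_t + noise_t))` where
#' the level drops by `shared_covid_drop * control_mean` from the
#' intervention start week onward and noise is iid Gaussian.
#'
#' @param config a [synthetic_config()]
#' @param seed integer RNG seed
#' @return list: `series` (a [weekly_series()]) and `truth` (level, seasonal
#'   and pre-rounding values)
#' @export
gen_control_series <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  Tn <- config$n_weeks
  t_idx <- seq_len(Tn)
  drop_start <- week_index_of(config$intervention$start_date, config$anchor_date)
  level <- rep(config$control_mean, Tn)
  if (drop_start <= Tn)
    level[drop_start:Tn] <- level[drop_start:Tn] -
      config$shared_covid_drop * config$control_mean
  seasonal <- config$seasonal_amplitude * sin(2 * pi * (t_idx - 1) / 52)
  set.seed(stage_seed(seed, "control"))
  noise <- stats::rnorm(Tn, 0, config$control_sd)
  raw <- level + seasonal + noise
  counts <- round(pmax(0, raw))
  list(series = weekly_series(counts, config$anchor_date, "control"),
       truth = list(level = level, seasonal = seasonal, pre_rounding = raw,
                    drop_start_week = drop_start))
}

# simulate subset-AR noise at stationarity via a discarded warm-up stretch
sim_subset_ar <- function(n, phi, lags, innovation_sd, warmup = 300L) {
  maxlag <- if (length(lags)) max(lags) else 0L
  phi_full <- .expand_lags(phi, lags, maxlag)
  eps <- stats::rnorm(n + warmup, 0, innovation_sd)
  if (maxlag == 0) return(eps[warmup + seq_len(n)])
  x <- stats::filter(eps, phi_full, method = "recursive")
  as.numeric(x[warmup + seq_len(n)])
}

#' Generate an aligned dependent/control pair with full truth record
#'
#' The dependent series is
#' `round(max(0, alpha + beta * control_t + omega * I_t + outliers_t + N_t))`
#' with `N_t` subset-AR noise; the intercept `alpha` is chosen so the
#' pre-intervention expected dependent mean equals `dependent_mean_target`.
#'
#' @inheritParams gen_control_series
#' @return list: `pair` (a [series_pair()]) and `truth` (all realized
#'   parameters, the indicator, injected outliers, noise-free expectation and
#'   pre-rounding series)
#' @export
gen_pair <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  ctrl <- gen_control_series(config, seed)
  Tn <- config$n_weeks
  alpha <- config$dependent_mean_target - config$beta_control * config$control_mean
  ind <- make_indicator(config$intervention, config$anchor_date)
  outlier_effect <- numeric(Tn)
  for (o in config$injected_outliers) {
    outlier_effect <- outlier_effect +
      o$magnitude * outlier_regressor(o$type, o$week, delta = o$delta %||% 0.7,
                                      series_length = Tn)
  }
  lags <- as.integer(names(config$phi))
  set.seed(stage_seed(seed, "noise"))
  noise <- sim_subset_ar(Tn, unname(config$phi), lags, config$innovation_sd)
  expected <- alpha + config$beta_control * ctrl$series$counts +
    config$omega * ind + outlier_effect
  raw <- expected + noise
  counts <- round(pmax(0, raw))
  dep <- weekly_series(counts, config$anchor_date, "dependent")
  truth <- list(alpha = alpha, beta_control = config$beta_control,
                omega = config$omega, phi = config$phi,
                innovation_sd = config$innovation_sd,
                indicator = ind,
                injected_outliers = config$injected_outliers,
                expected = expected, pre_rounding = raw,
                noise = noise, control_truth = ctrl$truth,
                seed = as.integer(seed))
  list(pair = series_pair(dep, ctrl$series), truth = truth)
}

.AGE_BANDS <- data.frame(lo = c(18L, 35L, 45L, 55L, 65L),
                         hi = c(34L, 44L, 54L, 64L, 90L),
                         share = c(25.86, 20.43, 23.24, 18.06, 12.41) / 100)
.SEX_SHARE <- c(female = 0.5520, male = 0.4476, unknown = 0.0004)

#' Generate encounter-level records consistent with a weekly-count truth
#'
#' Emits one record per counted visit (visit dates uniform within the week;
#' dependent-series visits carry restricted-scope payer, control-series
#' visits full-scope payer; all Latino adults, treat-and-release), plus a
#' configurable fraction of decoy records that each fail at least one
#' inclusion criterion (minor age, non-Latino ethnicity, other payer, or
#' inpatient disposition). Binning the non-decoy records reproduces the
#' weekly truth exactly.
#'
#' @inheritParams gen_control_series
#' @return list: `records` (data.frame with an extra `is_decoy` logical and
#'   `group` column), `pair`, `truth`
#' @export
gen_encounter_records <- function(config, seed = 1L) {
  gp <- gen_pair(config, seed)
  Tn <- config$n_weeks
  starts <- week_starts(gp$pair$dependent)

  set.seed(stage_seed(seed, "encounters"))
  make_group <- function(series, payer, group) {
    n_w <- series$counts
    n <- sum(n_w)
    if (n == 0) return(NULL)
    wk <- rep(seq_len(Tn), n_w)
    dates <- starts[wk] + sample(0:6, n, replace = TRUE)
    band <- sample(nrow(.AGE_BANDS), n, replace = TRUE, prob = .AGE_BANDS$share)
    ages <- .AGE_BANDS$lo[band] +
      floor(stats::runif(n) * (.AGE_BANDS$hi[band] - .AGE_BANDS$lo[band] + 1L))
    data.frame(visit_date = dates,
               ethnicity = "latino",
               age_years = as.integer(ages),
               sex = sample(names(.SEX_SHARE), n, replace = TRUE, prob = .SEX_SHARE),
               payer = payer,
               disposition = "treat_release",
               group = group, is_decoy = FALSE)
  }
  recs <- rbind(make_group(gp$pair$dependent, "restricted_medical", "dependent"),
                make_group(gp$pair$control, "full_medical", "control"))

  n_decoy <- as.integer(round(config$decoy_fraction * nrow(recs)))
  if (n_decoy > 0) {
    set.seed(stage_seed(seed, "decoys"))
    mode <- sample(c("minor", "non_latino", "payer_other", "inpatient"),
                   n_decoy, replace = TRUE)
    dates <- config$anchor_date + sample(0:(7L * Tn - 1L), n_decoy, replace = TRUE)
    dec <- data.frame(visit_date = dates,
                      ethnicity = ifelse(mode == "non_latino", "non_latino", "latino"),
                      age_years = ifelse(mode == "minor",
                                         sample(1:17, n_decoy, replace = TRUE),
                                         sample(18:90, n_decoy, replace = TRUE)),
                      sex = sample(names(.SEX_SHARE), n_decoy, replace = TRUE,
                                   prob = .SEX_SHARE),
                      payer = ifelse(mode == "payer_other", "other",
                                     sample(c("restricted_medical", "full_medical"),
                                            n_decoy, replace = TRUE)),
                      disposition = ifelse(mode == "inpatient", "inpatient",
                                           "treat_release"),
                      group = "decoy", is_decoy = TRUE)
    recs <- rbind(recs, dec)
  }
  recs <- recs[order(recs$visit_date), ]
  rownames(recs) <- NULL
  gp$truth$n_decoys <- n_decoy
  list(records = recs, pair = gp$pair, truth = gp$truth)
}

#' Write a generator truth record to JSON
#' @param truth truth list from [gen_pair()] / [gen_encounter_records()]
#' @param path output path
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       Date = "ISO8601")
  invisible(path)
}
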