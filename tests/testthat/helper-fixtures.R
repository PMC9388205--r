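# Shared fixtures, all generated in code.

ANCHOR <- as.Date("2018-01-05")

# default study-condition configuration and its intervention indicator
default_cfg <- function(...) synthetic_config(...)

default_indicator <- function(cfg = default_cfg()) {
  make_indicator(cfg$intervention, cfg$anchor_date)
}

default_spec <- function(cfg = default_cfg()) {
  transfer_model_spec(noise = noise_spec(c(1, 5)),
                      intervention = default_indicator(cfg))
}

# a mixed encounter-record fixture with known composition, for filter tests
random_encounters <- function(n, seed) {
  set.seed(seed)
  data.frame(
    visit_date = ANCHOR + sample(0:(7 * 142 - 1), n, replace = TRUE),
    ethnicity = sample(c("latino", "non_latino", "unknown"), n, TRUE,
                       prob = c(0.7, 0.25, 0.05)),
    age_years = sample(0:95, n, TRUE),
    sex = sample(c("female", "male", "unknown"), n, TRUE, c(0.55, 0.44, 0.01)),
    payer = sample(c("restricted_medical", "full_medical", "other"), n, TRUE,
                   prob = c(0.45, 0.45, 0.10)),
    disposition = sample(c("treat_release", "inpatient"), n, TRUE, c(0.85, 0.15))
  )
}

# stationary subset-AR draw with unit innovations (uses the ambient RNG state)
sim_ar_fixture <- function(phi_full, n) {
  as.numeric(stats::filter(rnorm(n + 300), phi_full,
                           method = "recursive"))[301:(n + 300)]
}

# materialize one encounter row per counted visit at the week-start date
pair_to_records <- function(pair, dep_attrs, ctl_attrs) {
  starts <- week_starts(pair$dependent)
  mk <- function(series, attrs) {
    n_w <- series$counts
    data.frame(visit_date = rep(starts, n_w),
               ethnicity = attrs$ethnicity, age_years = 40L, sex = "female",
               payer = attrs$payer, disposition = "treat_release")
  }
  rbind(mk(pair$dependent, dep_attrs), mk(pair$control, ctl_attrs))
}
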