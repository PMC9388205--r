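#' Descriptive cohort table
#'
#' Counts and percentages of encounter records by payer group, sex and age
#' band, per calendar year and in total, in the style of a study's "Table 1".
#' Age bands use half-open intervals [18,35), [35,45), [45,55), [55,65),
#' [65,+). Percentages are within category and year and sum to 100.
#'
#' @param records filtered encounter records
#' @return data.frame `category, level, year, n, pct` (year `"Total"`
#'   included); empty with a warning if no records
#' @export
describe_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    warning("no records to describe")
    return(data.frame(category = character(0), level = character(0),
                      year = character(0), n = integer(0), pct = numeric(0)))
  }
  yr <- format(as_date_strict(records$visit_date, "visit_date"), "%Y")
  payer_lab <- c(restricted_medical = "undocumented (restricted payer)",
                 full_medical = "full-scope payer",
                 other = "other payer")
  age_band <- cut(records$age_years, breaks = c(18, 35, 45, 55, 65, Inf),
                  labels = c("18-34", "35-44", "45-55", "55-64", "65+"),
                  right = FALSE)
  dims <- list(payer = payer_lab[records$payer],
               sex = records$sex,
               age = as.character(age_band))
  one <- function(category, values, years) {
    do.call(rbind, lapply(c(sort(unique(years)), "Total"), function(y) {
      v <- if (y == "Total") values else values[years == y]
      tab <- table(v)
      data.frame(category = category, level = names(tab), year = y,
                 n = as.integer(tab), pct = 100 * as.integer(tab) / sum(tab))
    }))
  }
  out <- do.call(rbind, lapply(names(dims), function(nm) one(nm, dims[[nm]], yr)))
  rownames(out) <- NULL
  out
}

#' Re-run the pipeline under a sensitivity variant
#'
#' * `include_inpatient` — widens the disposition filter to include visits
#'   ending in a hospital stay.
#' * `step_switch` — replaces the pulse indicator with a sustained step coded
#'   1 from the intervention start through the series end.
#' * `alternate_pair` — swaps the comparison: Latino full-scope-payer visits
#'   become the dependent series and non-Latino full-scope-payer visits the
#'   control (requires encounter records including non-Latino patients).
#'
#' @param records encounter-record data.frame (a [series_pair()] is accepted
#'   for `step_switch` only)
#' @param config a [pipeline_config()]
#' @param variant one of `"include_inpatient"`, `"step_switch"`,
#'   `"alternate_pair"`
#' @return an `its_report` labeled with the variant
#' @export
run_sensitivity <- function(records, config = pipeline_config(),
                            variant = c("include_inpatient", "step_switch",
                                        "alternate_pair")) {
  variant <- match.arg(variant)
  cfg <- config
  input <- records
  if (variant == "include_inpatient") {
    if (inherits(records, "series_pair"))
      stop("include_inpatient requires encounter-level records")
    cfg$filter$dispositions_keep <-
      unique(c(cfg$filter$dispositions_keep, "inpatient"))
  } else if (variant == "step_switch") {
    cfg$intervention <- intervention_spec("step", config$intervention$start_date,
                                          series_length = config$n_weeks)
  } else {  # alternate_pair
    if (inherits(records, "series_pair"))
      stop("alternate_pair requires encounter-level records")
    fs <- cfg$filter
    fs$ethnicity_keep <- c("latino", "non_latino")
    fs$payer_keep <- "full_medical"
    kept <- filter_encounters(records, fs)
    non_latino <- kept[kept$ethnicity == "non_latino", , drop = FALSE]
    if (nrow(non_latino) == 0)
      stop("alternate_pair requires non-Latino records in the input")
    dep <- bin_weekly(kept[kept$ethnicity == "latino", , drop = FALSE],
                      cfg$anchor_date, cfg$n_weeks, "Latino full-scope payer")
    ctl <- bin_weekly(non_latino, cfg$anchor_date, cfg$n_weeks,
                      "non-Latino full-scope payer")
    input <- series_pair(dep, ctl)
  }
  report <- run_pipeline(input, cfg)
  report$variant <- variant
  report
}
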