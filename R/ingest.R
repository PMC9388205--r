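#' Weekly binning and encounter-level ingestion
#'
#' Encounter-level records (one row per emergency-department visit) are
#' filtered by inclusion criteria and aggregated to 7-day "weeks" anchored on
#' a Friday: week \eqn{w} covers the half-open interval
#' \eqn{[\mathrm{anchor} + 7(w-1),\ \mathrm{anchor} + 7w)} in calendar days,
#' so a Friday opens each week and the following Thursday closes it.
#' Week indices are 1-based.
#'
#' @name ingest
NULL

.WEEK_DAYS <- 7L

#' Is a date a Friday?
#' @param date a `Date`
#' @return logical
#' @keywords internal
is_friday <- function(date) as.POSIXlt(date)$wday == 5L

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(d))) stop("invalid ", what, ": ", paste(x[is.na(d)], collapse = ", "))
  d
}

#' Default inclusion filter
#'
#' Adults (18+), self-reported Latino ethnicity, restricted- or full-scope
#' Medicaid payer, treat-and-release disposition. A sensitivity variant adds
#' inpatient dispositions via `dispositions_keep`.
#'
#' @param min_age minimum age in whole years (inclusive)
#' @param ethnicity_keep ethnicity categories retained
#' @param payer_keep payer categories retained
#' @param dispositions_keep disposition categories retained
#' @return a `filter_spec` list
#' @export
filter_spec <- function(min_age = 18L,
                        ethnicity_keep = "latino",
                        payer_keep = c("restricted_medical", "full_medical"),
                        dispositions_keep = "treat_release") {
  stopifnot(length(ethnicity_keep) > 0, length(payer_keep) > 0,
            length(dispositions_keep) > 0, min_age >= 0)
  structure(list(min_age = as.integer(min_age),
                 ethnicity_keep = ethnicity_keep,
                 payer_keep = payer_keep,
                 dispositions_keep = dispositions_keep),
            class = "filter_spec")
}

#' Filter encounter records by inclusion criteria
#'
#' Applies the age / ethnicity / payer / disposition inclusion rules and
#' reports how many records each criterion removed (attrition accounting).
#' Criteria are applied jointly; the per-criterion counts attribute a removed
#' record to every criterion it fails.
#'
#' @param records data.frame with columns `visit_date`, `ethnicity`,
#'   `age_years`, `sex`, `payer`, `disposition`
#' @param spec a [filter_spec()]
#' @return the qualifying rows, original order preserved, with an attribute
#'   `removed` (named integer vector of per-criterion removal counts)
#' @export
filter_encounters <- function(records, spec = filter_spec()) {
  stopifnot(is.data.frame(records), nrow(records) > 0, inherits(spec, "filter_spec"))
  need <- c("visit_date", "ethnicity", "age_years", "sex", "payer", "disposition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$age_years < 0)) stop("negative age_years")

  fail_age  <- records$age_years < spec$min_age
  fail_eth  <- !(records$ethnicity %in% spec$ethnicity_keep)
  fail_pay  <- !(records$payer %in% spec$payer_keep)
  fail_disp <- !(records$disposition %in% spec$dispositions_keep)
  keep <- !(fail_age | fail_eth | fail_pay | fail_disp)

  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no records pass the inclusion filter")
  attr(out, "removed") <- c(age = sum(fail_age), ethnicity = sum(fail_eth),
                            payer = sum(fail_pay), disposition = sum(fail_disp))
  out
}

#' 1-based week index of a date relative to a Friday anchor
#'
#' @param date calendar date(s) (`Date` or ISO-8601 string)
#' @param anchor_date the Friday opening week 1
#' @return integer week index; week 1 starts on `anchor_date`
#' @export
week_index_of <- function(date, anchor_date) {
  date <- as_date_strict(date)
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  if (!is_friday(anchor_date)) stop("anchor_date is not a Friday: ", anchor_date)
  if (any(date < anchor_date)) stop("date precedes the anchor date")
  1L + as.integer(floor(as.numeric(date - anchor_date) / .WEEK_DAYS))
}

#' Number of whole weeks in a Friday-to-Thursday span
#'
#' @param start_date a Friday
#' @param end_date the Thursday closing the final week
#' @return integer number of 7-day periods
#' @export
span_weeks <- function(start_date, end_date) {
  start_date <- as_date_strict(start_date, "start_date")
  end_date <- as_date_strict(end_date, "end_date")
  if (!is_friday(start_date)) stop("start_date is not a Friday: ", start_date)
  if (as.POSIXlt(end_date)$wday != 4L) stop("end_date is not a Thursday: ", end_date)
  if (end_date <= start_date) stop("end_date must follow start_date")
  days <- as.numeric(end_date - start_date) + 1
  if (days %% .WEEK_DAYS != 0) stop("span is not a whole number of weeks")
  as.integer(days / .WEEK_DAYS)
}

#' Construct a weekly count series
#'
#' @param counts non-negative integer counts, week 1..T
#' @param anchor_date the Friday opening week 1
#' @param group_label text label for the group counted
#' @return a `weekly_series` object
#' @export
weekly_series <- function(counts, anchor_date, group_label = "series") {
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  if (!is_friday(anchor_date)) stop("anchor_date is not a Friday: ", anchor_date)
  if (length(counts) < 1 || any(counts < 0)) stop("counts must be non-negative, length >= 1")
  structure(list(counts = as.numeric(counts), anchor_date = anchor_date,
                 group_label = group_label),
            class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("<weekly_series> %s: %d weeks from %s (mean %.2f, sd %.2f)\n",
              x$group_label, length(x$counts), format(x$anchor_date),
              mean(x$counts), stats::sd(x$counts)))
  invisible(x)
}

#' Start date of each week in a series
#' @param x a `weekly_series`
#' @return `Date` vector, one Friday per week
#' @export
week_starts <- function(x) {
  x$anchor_date + .WEEK_DAYS * (seq_along(x$counts) - 1L)
}

#' Aggregate encounter records to a Friday-anchored weekly series
#'
#' Sums records per 7-day bin; weeks with no records get count 0, and the
#' total count is conserved. Interior zero weeks surrounded by busier
#' neighbours are reported as a warning (`gap_floor` sets "busier").
#'
#' @param records data.frame with a `visit_date` column
#' @param anchor_date the Friday opening week 1
#' @param n_weeks number of weeks in the span
#' @param group_label label for the output series
#' @param gap_floor warn about an interior zero week whose neighbours both
#'   exceed this count
#' @return a [weekly_series()]
#' @export
bin_weekly <- function(records, anchor_date, n_weeks, group_label = "series",
                       gap_floor = 10) {
  anchor_date <- as_date_strict(anchor_date, "anchor_date")
  n_weeks <- as.integer(n_weeks)
  stopifnot(n_weeks >= 1)
  counts <- numeric(n_weeks)
  if (nrow(records) > 0) {
    d <- as_date_strict(records$visit_date, "visit_date")
    last <- anchor_date + .WEEK_DAYS * n_weeks - 1L
    bad <- d < anchor_date | d > last
    if (any(bad)) stop("record dated outside the span: ", format(d[bad][1]))
    w <- week_index_of(d, anchor_date)
    tab <- tabulate(w, nbins = n_weeks)
    counts <- as.numeric(tab)
  }
  if (n_weeks >= 3) {
    mid <- 2:(n_weeks - 1)
    gap <- counts[mid] == 0 & counts[mid - 1] > gap_floor & counts[mid + 1] > gap_floor
    if (any(gap)) warning("interior zero-count week(s) at index: ",
                          paste(mid[gap], collapse = ", "))
  }
  weekly_series(counts, anchor_date, group_label)
}

#' Pair a dependent and a control weekly series
#'
#' Both series must share the anchor date and length; the control series is
#' the contemporaneous comparator that absorbs shared trends, seasonality and
#' common shocks.
#'
#' @param dependent,control [weekly_series()] objects
#' @return a `series_pair`
#' @export
series_pair <- function(dependent, control) {
  stopifnot(inherits(dependent, "weekly_series"), inherits(control, "weekly_series"))
  if (dependent$anchor_date != control$anchor_date)
    stop("series anchor dates differ")
  if (length(dependent$counts) != length(control$counts))
    stop("series lengths differ")
  structure(list(dependent = dependent, control = control), class = "series_pair")
}

#' @export
print.series_pair <- function(x, ...) {
  cat(sprintf("<series_pair> %d weeks from %s\n  dependent: %s\n  control:   %s\n",
              length(x$dependent$counts), format(x$dependent$anchor_date),
              x$dependent$group_label, x$control$group_label))
  invisible(x)
}

#' Read encounter-level CSV
#'
#' Expects header `visit_date,ethnicity,age_years,sex,payer,disposition` with
#' ISO-8601 dates.
#' @param path CSV file path
#' @return data.frame of encounter records
#' @export
read_encounters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("visit_date", "ethnicity", "age_years", "sex", "payer", "disposition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("encounter CSV missing columns: ", paste(miss, collapse = ", "))
  df$visit_date <- as_date_strict(df$visit_date, "visit_date")
  df
}

#' Read / write a paired weekly-series CSV
#'
#' Dialect: `week_index,week_start_date,count_dependent,count_control`.
#' @param path CSV file path
#' @param labels group labels for the two series (read only)
#' @return a [series_pair()]
#' @export
read_series_pair <- function(path, labels = c("dependent", "control")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("week_index", "week_start_date", "count_dependent", "count_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weekly CSV missing columns: ", paste(miss, collapse = ", "))
  df <- df[order(df$week_index), ]
  if (!identical(as.integer(df$week_index), seq_len(nrow(df))))
    stop("week_index must be 1..T without gaps")
  anchor <- as_date_strict(df$week_start_date[1], "week_start_date")
  series_pair(weekly_series(df$count_dependent, anchor, labels[1]),
              weekly_series(df$count_control, anchor, labels[2]))
}

#' @rdname read_series_pair
#' @param pair a [series_pair()]
#' @export
write_series_pair <- function(pair, path) {
  stopifnot(inherits(pair, "series_pair"))
  df <- data.frame(week_index = seq_along(pair$dependent$counts),
                   week_start_date = format(week_starts(pair$dependent)),
                   count_dependent = pair$dependent$counts,
                   count_control = pair$control$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
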