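test_that("week indexing follows the half-open Friday-to-Friday convention", {
  expect_identical(week_index_of("2018-01-05", ANCHOR), 1L)
  # study-period landmarks
  expect_identical(week_index_of("2020-05-15", ANCHOR), 124L)
  expect_identical(week_index_of("2020-05-21", ANCHOR), 124L)
  expect_identical(week_index_of("2019-07-19", ANCHOR), 81L)
  expect_identical(week_index_of("2019-07-25", ANCHOR), 81L)
  # day-count oracle: 2018-01-05 .. 2020-03-13 is 798 days; floor(798/7) = 114
  expect_identical(as.numeric(as.Date("2020-03-13") - ANCHOR), 798)
  expect_identical(week_index_of("2020-03-13", ANCHOR), 115L)

  expect_error(week_index_of("2018-01-04", ANCHOR), "precedes")
  expect_error(week_index_of("2018-01-10", "2018-01-06"), "not a Friday")

  # non-decreasing, +1 exactly every 7 days
  dates <- ANCHOR + 0:70
  idx <- week_index_of(dates, ANCHOR)
  expect_true(all(diff(idx) >= 0))
  expect_identical(week_index_of(dates + 7L, ANCHOR), idx + 1L)
})

test_that("span_weeks counts whole Friday-to-Thursday weeks", {
  expect_identical(span_weeks("2018-01-05", "2018-01-11"), 1L)
  expect_identical(span_weeks("2018-01-05", "2020-09-24"), 142L)
  # 2020-03-13 .. 2020-05-14 is 63 days -> 9 weeks
  expect_identical(span_weeks("2020-03-13", "2020-05-14"), 9L)
  expect_error(span_weeks("2018-01-06", "2018-01-11"), "not a Friday")
  expect_error(span_weeks("2018-01-05", "2018-01-12"), "not a Thursday")
  expect_error(span_weeks("2018-01-05", "2018-01-04"), "follow")
})

test_that("inclusion filter applies all criteria and accounts for removals", {
  rec <- random_encounters(40, seed = 1)
  rec$age_years[1] <- 17L   # below the adult boundary
  rec$payer[2] <- "other"
  out <- filter_encounters(rec, filter_spec())
  expect_false(1 %in% as.integer(rownames(out)))
  expect_false(2 %in% as.integer(rownames(out)))
  expect_true(all(out$age_years >= 18))
  expect_true(all(out$payer %in% c("restricted_medical", "full_medical")))
  expect_true(all(out$ethnicity == "latino"))
  expect_true(all(out$disposition == "treat_release"))
})

test_that("filter matches an independent brute-force scan on a 1000-record fixture", {
  rec <- random_encounters(1000, seed = 77)
  # oracle: row-by-row rule evaluation, independent of the implementation
  keep_oracle <- logical(1000)
  for (i in seq_len(1000)) {
    r <- rec[i, ]
    keep_oracle[i] <- r$age_years >= 18 && r$ethnicity == "latino" &&
      r$payer %in% c("restricted_medical", "full_medical") &&
      r$disposition == "treat_release"
  }
  out <- filter_encounters(rec, filter_spec())
  expect_identical(nrow(out), sum(keep_oracle))
  expect_identical(as.integer(rownames(out)), which(keep_oracle))  # order preserved
  removed <- attr(out, "removed")
  expect_identical(unname(removed["age"]), sum(rec$age_years < 18))
  expect_identical(unname(removed["ethnicity"]), sum(rec$ethnicity != "latino"))
})

test_that("weekly binning conserves counts and zero-fills empty weeks", {
  empty <- data.frame(visit_date = as.Date(character(0)))
  ws <- bin_weekly(empty, ANCHOR, 5)
  expect_identical(ws$counts, rep(0, 5))

  # a Thursday closes week 1
  thu <- data.frame(visit_date = rep(as.Date("2018-01-11"), 3))
  expect_identical(bin_weekly(thu, ANCHOR, 2)$counts, c(3, 0))

  rec <- random_encounters(500, seed = 3)
  ws <- bin_weekly(rec, ANCHOR, 142)
  expect_identical(sum(ws$counts), 500)
  # independent tally by date arithmetic
  tallied <- table(factor(1 + floor(as.numeric(rec$visit_date - ANCHOR) / 7),
                          levels = 1:142))
  expect_identical(ws$counts, as.numeric(tallied))

  late <- data.frame(visit_date = ANCHOR + 7 * 142)
  expect_error(bin_weekly(late, ANCHOR, 142), "2020-09-25")
})

test_that("series pair construction enforces alignment", {
  a <- weekly_series(1:10, ANCHOR, "a")
  b <- weekly_series(1:10, ANCHOR, "b")
  expect_s3_class(series_pair(a, b), "series_pair")
  expect_error(series_pair(a, weekly_series(1:9, ANCHOR)), "length")
  expect_error(series_pair(a, weekly_series(1:10, ANCHOR + 7)), "anchor")
  expect_error(weekly_series(1:5, "2018-01-06"), "Friday")
  expect_error(weekly_series(c(1, -1), ANCHOR), "non-negative")
})

test_that("weekly-series CSV round-trips", {
  cfg <- default_cfg()
  gp <- gen_pair(cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_pair(gp$pair, path)
  back <- read_series_pair(path)
  expect_identical(back$dependent$counts, gp$pair$dependent$counts)
  expect_identical(back$control$counts, gp$pair$control$counts)
  expect_identical(back$dependent$anchor_date, gp$pair$dependent$anchor_date)
})

test_that("encounter CSV reader validates its header and dates", {
  rec <- random_encounters(20, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE)
  back <- read_encounters(path)
  expect_identical(back$visit_date, rec$visit_date)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec[, -1], bad, row.names = FALSE)
  expect_error(read_encounters(bad), "missing columns")
})
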