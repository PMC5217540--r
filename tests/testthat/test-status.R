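reg <- default_codelist()

test_that("the seven census scenarios classify as narrated", {
  ev <- scenario_timeline()
  censuses <- scenario_censuses()
  got <- vapply(censuses, function(d) classify_at(ev, reg, d), character(1))
  expect_equal(unname(got),
               c("UNKNOWN_SMOKING_STATUS", "EX_SMOKER", "RELAPSED_SMOKER",
                 "SMOKER", "SMOKER", "EX_SMOKER", "EX_SMOKER"))
})

test_that("likely-smoker and empty-record cases resolve first", {
  empty <- data.frame(patient_id = character(0),
                      event_date = as.Date(character(0)),
                      code = character(0))
  for (d in as.Date(c("1990-01-01", "2010-01-01", "2030-01-01"))) {
    expect_equal(classify_at(empty, reg, as.Date(d, origin = "1970-01-01")),
                 "NO_INFORMATION")
  }
  smoker_only <- data.frame(patient_id = "p",
                            event_date = as.Date(c("2010-01-01",
                                                   "2012-01-01")),
                            code = c("137R.", "du331"))
  expect_equal(classify_at(smoker_only, reg, as.Date("2005-01-01")),
               "LIKELY_SMOKER")
  mixed <- rbind(smoker_only,
                 data.frame(patient_id = "p",
                            event_date = as.Date("2013-01-01"),
                            code = "137F."))
  expect_equal(classify_at(mixed, reg, as.Date("2005-01-01")),
               "UNKNOWN_SMOKING_STATUS")
})

test_that("temporal-check variant differs only where never-smoker stands", {
  # never span containing the census, with earlier ex evidence
  ev <- data.frame(patient_id = "p",
                   event_date = as.Date(c("2000-01-01", "2005-01-01",
                                          "2010-01-01")),
                   code = c("137F.", "1371.", "1371."))
  census <- as.Date("2007-01-01")
  expect_equal(classify_at(ev, reg, census), "EX_SMOKER")
  expect_equal(classify_at(ev, reg, census, temporal = FALSE),
               "NEVER_SMOKER")

  # relapse detection is retained without temporal checking
  overlap <- scenario_timeline()
  expect_equal(classify_at(overlap, reg, as.Date("2004-06-01"),
                           temporal = FALSE), "RELAPSED_SMOKER")

  # without a NEVER category the variants agree
  no_never <- overlap[overlap$code != "1371.", ]
  for (d in scenario_censuses()) {
    expect_equal(classify_at(no_never, reg, d),
                 classify_at(no_never, reg, d, temporal = FALSE))
  }
})

test_that("classifier agrees with the brute-force scenario oracle", {
  set.seed(20)
  n_cases <- 3000
  mismatches <- 0
  for (i in seq_len(n_cases)) {
    ev <- random_events(sample(0:8, 1))
    census <- random_census()
    s <- readsmoke:::category_summary(ev$event_date, ev$category)
    if (!identical(classify_full(s, ev, census),
                   oracle_classify(ev, census)) ||
        !identical(classify_full(s, ev, census, temporal_check = FALSE),
                   oracle_classify(ev, census, temporal = FALSE))) {
      mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("classifier is total, conflict-monotone and variant-consistent", {
  set.seed(21)
  n_cases <- 4000
  statuses <- c("NO_INFORMATION", "UNKNOWN_SMOKING_STATUS", "NEVER_SMOKER",
                "EX_SMOKER", "RELAPSED_SMOKER", "LIKELY_SMOKER", "SMOKER")
  violations <- c(total = 0, monotone = 0, variant = 0)
  for (i in seq_len(n_cases)) {
    ev <- random_events(sample(0:6, 1))
    census <- random_census()
    s <- readsmoke:::category_summary(ev$event_date, ev$category)
    full <- classify_full(s, ev, census)
    nt <- classify_full(s, ev, census, temporal_check = FALSE)
    if (!(full %in% statuses)) violations[["total"]] <- 1 + violations[["total"]]
    # never-smoker is impossible once ex/smoker evidence precedes the census
    smoke_dates <- ev$event_date[ev$category %in% c("EX", "SMOKER")]
    if (length(smoke_dates) > 0 && min(smoke_dates) <= census &&
        full == "NEVER_SMOKER") {
      violations[["monotone"]] <- 1 + violations[["monotone"]]
    }
    # the variants differ only when the no-temporal one says never-smoker
    if (full != nt && nt != "NEVER_SMOKER") {
      violations[["variant"]] <- 1 + violations[["variant"]]
    }
  }
  expect_equal(unname(violations), c(0, 0, 0))
})

test_that("nearest-status classification picks the closest code date", {
  mk <- function(dates, cats) data.frame(event_date = as.Date(dates),
                                         category = cats)
  census <- as.Date("2010-06-01")
  expect_equal(classify_nearest(mk(character(0), character(0)), census),
               "MISSING")
  expect_equal(classify_nearest(mk("1990-01-01", "NEVER"), census),
               "NEVER_SMOKER")
  expect_equal(classify_nearest(mk(c("2010-05-22", "2010-07-01"),
                                   c("SMOKER", "EX")), census), "SMOKER")
  # equidistant: the code on/before the census wins
  expect_equal(classify_nearest(mk(c("2010-05-22", "2010-06-11"),
                                   c("SMOKER", "EX")), census), "SMOKER")
  expect_equal(classify_nearest(mk(c("2010-05-22", "2010-06-11"),
                                   c("EX", "SMOKER")), census), "EX_SMOKER")
  # same-day conflict: smoker over ex over never
  expect_equal(classify_nearest(mk(c("2010-06-01", "2010-06-01"),
                                   c("NEVER", "EX")), census), "EX_SMOKER")

  # exact ties are too rare in daily-resolution cohorts to move agreement
  set.seed(7)
  cohort <- generate_cohort(cohort_params(n_patients = 400, seed = 7))
  ie <- informative_events(cohort$events, reg, status_only = TRUE)
  by_pat <- split(ie, ie$patient_id)
  census_tbl <- cohort$surveys
  tied <- vapply(census_tbl$patient_id, function(id) {
    ev <- by_pat[[id]]
    if (is.null(ev) || nrow(ev) < 2) return(FALSE)
    d <- abs(as.integer(ev$event_date -
                          census_tbl$survey_date[census_tbl$patient_id == id]))
    sum(d == min(d)) > 1
  }, logical(1))
  expect_lt(mean(tied), 0.01)
})

test_that("status collapse is total and maps as specified", {
  seven <- c("NO_INFORMATION", "UNKNOWN_SMOKING_STATUS", "NEVER_SMOKER",
             "EX_SMOKER", "RELAPSED_SMOKER", "LIKELY_SMOKER", "SMOKER")
  expect_equal(collapse_status(seven),
               c("MISSING", "MISSING", "NEVER_SMOKER", "EX_SMOKER",
                 "SMOKER", "SMOKER", "SMOKER"))
  expect_error(collapse_status("SOMETIMES"), "unknown status")
})

test_that("cohort classification matches per-patient classification", {
  set.seed(33)
  cohort <- generate_cohort(cohort_params(n_patients = 60, seed = 33))
  census <- as.Date("2012-07-01")
  res <- classify_cohort(cohort$events, reg, census, variant = "full")
  expect_equal(res$patient_id, sort(unique(cohort$events$patient_id)))
  for (id in sample(res$patient_id, 10)) {
    ev <- cohort$events[cohort$events$patient_id == id, ]
    expect_identical(res$status[res$patient_id == id],
                     classify_at(ev, reg, census))
  }
  # per-patient census table drives each patient's own date
  census_tbl <- data.frame(patient_id = res$patient_id[1:5],
                           census_date = as.Date("2005-03-01") + 1:5 * 400)
  res2 <- classify_cohort(cohort$events, reg, census_tbl, variant = "full")
  expect_equal(nrow(res2), 5)
  for (k in 1:5) {
    ev <- cohort$events[cohort$events$patient_id ==
                          census_tbl$patient_id[k], ]
    expect_identical(res2$status[k],
                     classify_at(ev, reg, census_tbl$census_date[k]))
  }
})
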