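test_that("event log round-trips through CSV losslessly", {
  log <- generate_log(packaged_profile("site_b", n_cases = 150, seed = 3))
  dir <- withr::local_tempdir()
  write_log(log, dir)
  back <- read_log(dir)
  expect_equal(as.data.frame(back$events), as.data.frame(log$events),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$cases), as.data.frame(log$cases),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$appointments),
               as.data.frame(log$appointments), ignore_attr = TRUE)
  expect_equal(as.data.frame(back$outcomes), as.data.frame(log$outcomes),
               ignore_attr = TRUE)
  expect_equal(load_report(back)$n_rejected, 0)

  # repaired logs keep both timestamps through the round trip
  rep <- impute_timestamps(corrupt_timestamps(
    log, 0.3, dist_spec("fixed", 500), seed = 9))
  dir2 <- withr::local_tempdir()
  write_log(rep$log, dir2)
  back2 <- read_log(dir2)
  expect_true(any(back2$events$imputed))
  expect_equal(as.data.frame(back2$events), as.data.frame(rep$log$events),
               ignore_attr = TRUE)
})

test_that("malformed movement rows are rejected and counted", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,activity,timestamp",
               "c1,referral_received,2020-01-01T00:00:00",
               ",assessment,2020-01-08T00:00:00",
               "c1,assessment,not-a-date",
               "c2,referral_received,2020-02-01T00:00:00"),
             file.path(dir, "movements.csv"))
  log <- read_log(dir)
  expect_equal(nrow(log$events), 2)
  rep <- load_report(log)
  expect_equal(rep$n_rejected, 2)
  expect_equal(rep$n_missing_case_id, 1)
  expect_equal(rep$n_bad_timestamp, 1)
})

test_that("a missing required column raises a schema error naming it", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,timestamp", "c1,2020-01-01T00:00:00"),
             file.path(dir, "movements.csv"))
  expect_error(read_log(dir), "activity")
})

test_that("order violations are exactly the events behind their running max", {
  log <- log_from_traces(list(
    c(referral = 0, assessment = 4/7, treatment = 2/7, discharged = 8/7),
    c(referral = 0, assessment = 1, discharged = 2)
  ))
  v <- detect_order_violations(log)
  expect_equal(nrow(v), 1)
  expect_equal(v$activity, "treatment")
  expect_equal(v$case_id, "c01")

  increasing <- log_from_traces(list(c(a = 0, b = 1, c = 2)))
  expect_equal(nrow(detect_order_violations(increasing)), 0)
})

test_that("only corrupted events can violate ordering on synthetic logs", {
  log <- generate_log(packaged_profile("site_b", n_cases = 400, seed = 21))
  truth <- log_truth(log)
  v <- detect_order_violations(log)
  flagged <- paste(v$case_id, v$source_order)
  corrupted <- paste(log$events$case_id, log$events$source_order)[truth$corrupted]
  expect_true(all(flagged %in% corrupted))
  # brute-force per-case scan agrees with the vectorised detector
  ev <- log$events[order(log$events$case_id, log$events$source_order), ]
  brute <- character()
  for (cid in unique(ev$case_id)) {
    ts <- as.numeric(ev$timestamp[ev$case_id == cid])
    so <- ev$source_order[ev$case_id == cid]
    if (length(ts) < 2) next
    for (j in 2:length(ts)) {
      if (ts[j] < max(ts[1:(j - 1)])) brute <- c(brute, paste(cid, so[j]))
    }
  }
  expect_setequal(flagged, brute)
})

test_that("LOCF repair replaces violations with the running maximum", {
  log <- log_from_traces(list(
    c(referral = 0, a = 4/7, b = 2/7, c = 8/7)  # days 0, 4, 2, 8
  ))
  out <- impute_timestamps(log)
  got_days <- as.numeric(difftime(out$log$events$timestamp,
                                  out$log$events$timestamp[1], units = "days"))
  expect_equal(got_days, c(0, 4, 4, 8))
  expect_equal(out$log$events$imputed, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$report$n_events_adjusted, 1)
  expect_equal(sum(out$report$adjustment_sizes_weeks), 2 / 7)
  # original timestamp retained on the repaired event
  expect_equal(out$log$events$original_timestamp[3], log$events$timestamp[3])
})

test_that("repair leaves clean logs untouched and reports all zeros", {
  log <- log_from_traces(list(c(a = 0, b = 1, c = 3), c(a = 0, b = 2)))
  out <- impute_timestamps(log)
  expect_equal(as.data.frame(out$log$events), as.data.frame(log$events))
  expect_equal(out$report$n_events_adjusted, 0)
  s <- out$report$summary
  expect_true(all(s$median[s$statistic == "adjustment_per_event_all"] == 0))
})

test_that("repair removes all violations and is idempotent", {
  log <- corrupt_timestamps(
    generate_log(packaged_profile("site_a", n_cases = 300, seed = 5)),
    rate = 0.2, magnitude_dist = dist_spec("lognormal", log(4), 1), seed = 6)
  out <- impute_timestamps(log)
  expect_equal(nrow(detect_order_violations(out$log)), 0)
  again <- impute_timestamps(out$log)
  expect_equal(again$report$n_events_adjusted, 0)
  expect_equal(as.data.frame(again$log$events), as.data.frame(out$log$events))
})

test_that("imputation report satisfies conservation identities", {
  log <- corrupt_timestamps(
    generate_log(packaged_profile("site_b", n_cases = 500, seed = 8)),
    rate = 0.1, magnitude_dist = dist_spec("lognormal", log(2), 1), seed = 9)
  rep <- impute_timestamps(log)$report
  expect_equal(sum(rep$per_case_counts), rep$n_events_adjusted)
  expect_equal(sum(rep$per_case_totals_weeks),
               sum(rep$adjustment_sizes_weeks))
  expect_lte(rep$n_events_adjusted, rep$n_events_total)
  expect_true(all(rep$adjustment_sizes_weeks >= 0))
  # median over all events is 0 whenever under half are adjusted
  frac <- rep$n_events_adjusted / rep$n_events_total
  expect_lt(frac, 0.5)
  s <- rep$summary
  expect_equal(s$median[s$statistic == "adjustment_per_event_all"], 0)
})

test_that("filter_cases keeps exactly the matching cases with their records", {
  log <- generate_log(packaged_profile("site_b", n_cases = 200, seed = 12))
  cutoff <- as.POSIXct("2020-06-01", tz = "UTC")
  out <- filter_cases(log, age >= 30, referral_date < cutoff)
  expected_ids <- log$cases$case_id[log$cases$age >= 30 &
                                      log$cases$referral_date < cutoff]
  expect_setequal(out$cases$case_id, expected_ids)
  expect_setequal(unique(out$events$case_id), expected_ids)
  expect_true(all(out$appointments$case_id %in% expected_ids))
  expect_true(all(out$outcomes$case_id %in% expected_ids))
  # tautological predicate is the identity
  same <- filter_cases(log, TRUE)
  expect_equal(nrow(same$cases), nrow(log$cases))
})

test_that("event_log validation rejects broken structure", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  expect_error(
    event_log(data.frame(case_id = "c1", activity = "a", timestamp = t0,
                         source_order = 2L)),
    "source_order")
  expect_error(
    event_log(data.frame(case_id = "c1", activity = "a", timestamp = t0),
              cases = data.frame(case_id = "other")),
    "unknown case")
})
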