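test_that("route enumeration ranks variants by frequency then label", {
  traces <- c(
    replicate(3, c(referral_received = 0, assessment_wl = 1, assessment = 4,
                   discharged = 6), simplify = FALSE),
    list(c(referral_received = 0, discharged = 1))
  )
  rs <- enumerate_routes(log_from_traces(traces))
  expect_equal(nrow(rs), 2)
  expect_equal(rs$n_cases, c(3L, 1L))
  expect_equal(rs$rank, 1:2)
  expect_equal(sum(rs$pct_of_all), 100)
  expect_equal(rs$route_class, c("no_treatment", "no_treatment"))
})

test_that("route classification implements the class partition rules", {
  roles <- default_stage_roles()
  cls <- classify_route_strings(c(
    "referral_received -> discharged",
    "referral_received -> assessment_wl -> discharged",
    "referral_received -> assessment_wl -> assessment -> discharged",
    "referral_received -> assessment_wl -> assessment -> step2_wl -> discharged",
    "referral_received -> assessment_wl -> assessment -> step2_wl -> step2_treatment -> discharged",
    "referral_received -> assessment_wl -> assessment -> step3_wl -> step3_treatment -> discharged",
    "referral_received -> assessment_wl -> assessment -> step3_wl -> discharged",
    paste("referral_received -> assessment_wl -> assessment -> step2_wl ->",
          "step2_treatment -> step3_wl -> step3_treatment -> discharged"),
    paste("referral_received -> assessment_wl -> assessment -> step2_wl ->",
          "step2_treatment -> step3_wl -> discharged")
  ), roles)
  expect_equal(cls, c("no_treatment", "attrition_assessment_wl",
                      "no_treatment", "attrition_step2_wl", "step2_only",
                      "step3_only", "attrition_step3_wl", "stepped_care",
                      "attrition_step3_wl"))
  expect_true(all(cls %in% careflow:::ROUTE_CLASSES))
})

test_that("per-route counts and outcome rates match brute-force recounts", {
  rs <- enumerate_routes(std_level_b()$log)
  truth <- std_site_a_log()$cases
  brute <- table(truth$true_route)
  expect_equal(sum(rs$n_cases), nrow(truth))
  for (i in seq_len(min(8, nrow(rs)))) {
    expect_equal(rs$n_cases[i], unname(brute[[rs$route[i]]]))
  }
  # the four outcome bins partition every route's cases
  sums <- rs$rate_recovered + rs$rate_not_recovered +
    rs$rate_not_at_caseness + rs$rate_unknown
  expect_true(all(abs(sums - 1) < 1e-9))
  # recovered counts per route agree with generator ground truth
  rec_brute <- tapply(truth$true_recovered, truth$true_route, sum)
  for (i in seq_len(min(8, nrow(rs)))) {
    expect_equal(round(rs$rate_recovered[i] * rs$n_cases[i]),
                 unname(rec_brute[[rs$route[i]]]))
  }
})

test_that("top-N plus other conserves cases and pools outcomes", {
  rs <- enumerate_routes(std_level_b()$log)
  tno <- top_n_with_other(rs, 5)
  expect_equal(nrow(tno$top), 5)
  expect_equal(sum(tno$top$n_cases) + tno$other$n_cases, sum(rs$n_cases))
  # pooled recovery rate equals a brute-force recount over pooled cases
  truth <- std_site_a_log()$cases
  pooled_ids <- truth$case_id[!truth$true_route %in% tno$top$route]
  expect_equal(tno$other$n_cases, length(pooled_ids))
  brute_rec <- mean(truth$true_recovered[truth$case_id %in% pooled_ids])
  expect_equal(tno$other$rate_recovered, brute_rec)
  # when n exceeds the variant count the aggregate is empty
  all_in <- top_n_with_other(rs, nrow(rs) + 5)
  expect_equal(all_in$other$n_cases, 0)
  expect_error(top_n_with_other(rs, 0), "n must be")
})

test_that("stepped-care rate reproduces the worked decompositions", {
  big <- stepped_care_rate(total_cases = 45401, common = 1117, uncommon = 390)
  expect_equal(big$total_stepped, 1507)
  expect_equal(big$pct, 3.32)
  small <- stepped_care_rate(total_cases = 12590, common = 365, uncommon = 162)
  expect_equal(small$total_stepped, 527)
  expect_equal(small$pct, 4.19)
  none <- stepped_care_rate(total_cases = 100, common = 0, uncommon = 0)
  expect_equal(none$pct, 0)
  expect_error(stepped_care_rate(total_cases = 0, common = 1, uncommon = 0),
               "total_cases")
})

test_that("stepped-care rate splits common from uncommon routes", {
  rs <- enumerate_routes(std_level_b()$log)
  truth <- std_site_a_log()$cases
  scr <- stepped_care_rate(rs, total_cases = nrow(truth), top_n = 10)
  expect_equal(scr$total_stepped, sum(truth$true_route_class == "stepped_care"))
  stepped_in_top <- rs$route_class == "stepped_care" & rs$rank <= 10
  expect_equal(scr$common, sum(rs$n_cases[stepped_in_top]))
  expect_equal(scr$common + scr$uncommon, scr$total_stepped)
})

test_that("wait comparison pairs treated routes with attrition counterparts", {
  fake <- tibble::tibble(
    rank = 1:4,
    route = c("r1", "r2", "r3", "r4"),
    route_class = c("step2_only", "attrition_step2_wl", "step3_only",
                    "attrition_step3_wl"),
    n_cases = c(100L, 50L, 40L, 20L),
    total_wait_median_weeks = c(13.3, 20.6, 34, 41.9)
  )
  wc <- wait_comparison(fake)
  expect_equal(wc$pairs$difference_weeks, c(7.3, 7.9))
  expect_equal(wc$step3_vs_step2_ratio, 2.6)
  # equal medians give difference 0 and ratio 1
  even <- fake
  even$total_wait_median_weeks <- c(10, 10, 10, 10)
  wc2 <- wait_comparison(even)
  expect_equal(wc2$pairs$difference_weeks, c(0, 0))
  expect_equal(wc2$step3_vs_step2_ratio, 1)
  # a missing counterpart is omitted with a note
  wc3 <- wait_comparison(fake[c(1, 3), ])
  expect_equal(nrow(wc3$pairs), 0)
  expect_match(wc3$notes[1], "step2")
})

test_that("attrition routes wait longer than treated routes by design", {
  rs <- enumerate_routes(std_level_b()$log)
  wc <- wait_comparison(rs)
  expect_equal(nrow(wc$pairs), 2)
  expect_true(all(wc$pairs$difference_weeks > 0))
  expect_gt(wc$step3_vs_step2_ratio, 1)
})

test_that("route plot data lays stages out by cumulative medians", {
  rs <- enumerate_routes(std_level_b()$log)
  tno <- top_n_with_other(rs, 6)
  pd <- export_route_plot_data(tno$top, tno$other)
  for (rt in unique(tno$top$route)) {
    rows <- pd[pd$route == rt, ]
    expect_equal(rows$offset_weeks, cumsum(c(0, head(rows$width_weeks, -1))))
    expect_equal(rows$stage, strsplit(rt, " -> ", fixed = TRUE)[[1]])
  }
  # single-stage route: one row at offset zero
  single <- enumerate_routes(log_from_traces(list(c(referral_received = 0))))
  pd1 <- export_route_plot_data(single)
  expect_equal(nrow(pd1), 1)
  expect_equal(pd1$offset_weeks, 0)
  # pooled aggregate appended as one full-width row
  expect_equal(sum(pd$route == "(other routes)"), 1)
  p <- plot_routes(pd)
  expect_s3_class(p, "ggplot")
})
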