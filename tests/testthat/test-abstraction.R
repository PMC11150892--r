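spec_demo <- abstraction_spec(
  name = "demo",
  rename_map = c("CBT v1" = "CBT", "CBT (old)" = "CBT"),
  subprocess_groups = list(step3_treatment = c("CBT", "counseling", "EMDR"),
                           discharged = c("discharge_planning", "discharged")),
  exclusions = c("step3_wl")
)

test_that("remap_stages merges labels without touching event counts", {
  log <- log_from_traces(list(
    c("referral" = 0, "CBT v1" = 2, "CBT (old)" = 3, "discharged" = 5),
    c("referral" = 0, "CBT" = 1, "discharged" = 4)
  ))
  out <- remap_stages(log, spec_demo)
  expect_equal(nrow(out$events), nrow(log$events))
  expect_setequal(unique(out$events$activity),
                  c("referral", "CBT", "discharged"))
  # empty map is the identity
  id <- remap_stages(log, abstraction_spec("none"))
  expect_equal(id$events, log$events)
})

test_that("collapse merges only consecutive same-subprocess runs", {
  log <- log_from_traces(list(
    c(assessment = 0, CBT = 2, CBT = 3, discharged = 6),
    c(discharge_planning = 0, discharged = 0.1),
    c(CBT = 0, other = 2, CBT = 4)
  ))
  out <- collapse_subprocesses(log, spec_demo)
  routes <- tapply(out$events$activity, out$events$case_id, paste,
                   collapse = " -> ")
  expect_equal(unname(routes[["c01"]]),
               "assessment -> step3_treatment -> discharged")
  expect_equal(unname(routes[["c02"]]), "discharged")
  # non-consecutive runs stay separate
  expect_equal(unname(routes[["c03"]]),
               "step3_treatment -> other -> step3_treatment")
  # the collapsed event keeps the run's first timestamp
  c1 <- out$events[out$events$case_id == "c01", ]
  expect_equal(as.numeric(difftime(c1$timestamp[2], c1$timestamp[1],
                                   units = "days")) / 7, 2)
})

test_that("collapse is idempotent and never increases event counts", {
  for (seed in 1:5) {
    set.seed(seed)
    log <- random_small_log(10, 6)
    spec <- abstraction_spec("p", subprocess_groups = list(grp = c("A", "B")))
    once <- collapse_subprocesses(log, spec)
    twice <- collapse_subprocesses(once, spec)
    expect_equal(twice$events, once$events)
    expect_lte(nrow(once$events), nrow(log$events))
    expect_equal(dplyr::n_distinct(once$events$case_id),
                 dplyr::n_distinct(log$events$case_id))
  }
})

test_that("exclude_stages removes exactly the excluded events", {
  log <- log_from_traces(list(
    c(referral = 0, step3_wl = 1, CBT = 5, discharged = 9),
    c(step3_wl = 0)
  ))
  out <- exclude_stages(log, spec_demo)
  expect_false(any(out$events$activity == "step3_wl"))
  expect_equal(nrow(out$events),
               sum(log$events$activity != "step3_wl"))
  # the case left empty is dropped and counted
  expect_equal(attr(out, "n_cases_dropped"), 1)
  expect_false("c02" %in% out$cases$case_id)
  # source_order renumbered contiguously
  expect_equal(out$events$source_order[out$events$case_id == "c01"], 1:3)
})

test_that("coverage filtering keeps the minimal prefix of ranked variants", {
  traces <- c(
    replicate(6, c(a = 0, b = 1), simplify = FALSE),
    replicate(3, c(a = 0, c = 1), simplify = FALSE),
    replicate(1, c(a = 0, d = 1), simplify = FALSE)
  )
  log <- log_from_traces(traces)
  res <- filter_by_coverage(log, 0.9)
  expect_equal(res$n_retained, 9)
  expect_equal(res$routes_kept, 2)
  all_kept <- filter_by_coverage(log, 1)
  expect_equal(all_kept$n_retained, 10)
  expect_error(filter_by_coverage(log, 0), "coverage")
})

test_that("coverage filter matches a brute-force prefix scan", {
  log <- std_level_b()$log
  routes <- tapply(log$events$activity, log$events$case_id, paste,
                   collapse = " -> ")
  counts <- sort(table(routes), decreasing = TRUE)
  # resolve count ties lexicographically, as the implementation documents
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  total <- length(routes)
  for (cov in c(0.5, 0.8, 0.95, 0.99)) {
    k <- which(cumsum(counts) / total >= cov)[1]
    expected_n <- sum(counts[1:k])
    res <- filter_by_coverage(log, cov)
    expect_equal(res$routes_kept, unname(k))
    expect_equal(res$n_retained, unname(expected_n))
    expect_gte(res$n_retained / total, cov)
  }
})

test_that("retained cases are non-decreasing in coverage", {
  log <- std_level_b()$log
  kept <- vapply(c(0.5, 0.7, 0.9, 1), function(cov) {
    filter_by_coverage(log, cov)$n_retained
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("apply_abstraction composes the steps in order and summarises", {
  rep <- std_repaired()
  res <- apply_abstraction(rep$log, packaged_abstraction("B"), coverage = 1)
  s <- res$summary
  # distinct route count never increases along rename -> collapse -> exclude
  routes_along <- s$n_routes[match(c("raw", "renamed", "collapsed", "excluded"),
                                   s$step)]
  expect_true(all(diff(routes_along) <= 0))
  # summary equals a brute-force recomputation on the final log
  final <- res$log
  expect_equal(s$n_stages[s$step == "covered"],
               length(unique(final$events$activity)))
  brute_routes <- length(unique(tapply(final$events$activity,
                                       final$events$case_id, paste,
                                       collapse = " -> ")))
  expect_equal(s$n_routes[s$step == "covered"], brute_routes)
  # level-B abstraction reduces the vocabulary to the canonical stages
  expect_setequal(unique(final$events$activity),
                  c("referral_received", "assessment_wl", "assessment",
                    "step2_wl", "step2_treatment", "step3_wl",
                    "step3_treatment", "discharged"))
})

test_that("abstracted observed routes agree with generator ground truth", {
  res <- std_level_b()
  obs <- tapply(res$log$events$activity, res$log$events$case_id, paste,
                collapse = " -> ")
  truth <- std_site_a_log()$cases
  expect_equal(as.character(obs[truth$case_id]), truth$true_route)
})

test_that("conflicting abstraction specs are rejected", {
  expect_error(
    abstraction_spec("x", subprocess_groups = list(a = "z", b = "z")),
    "two subprocess groups")
  expect_error(
    abstraction_spec("x", subprocess_groups = list(a = "z"),
                     exclusions = "a"),
    "overlap")
})
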