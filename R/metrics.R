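# Cohort-level service metrics: completion, recovery, missed appointments,
# coverage, flow breakdown, imputation rate, and a cohort summary.
#
# Every calculator returns its numerator and denominator alongside the
# rate so printed figures can be checked by recomputation.

#' Treatment completion rate
#'
#' Proportion of all referrals that attended at least two treatment
#' sessions. Appointment rows with a missing attendance flag are removed
#' before counting.
#'
#' @param log A `careflow_log`.
#' @return A list with `numerator`, `denominator`, `pct` (2 dp) and
#'   `completers` (their case ids).
#' @export
completion_rate <- function(log) {
  stopifnot(inherits(log, "careflow_log"))
  total <- nrow(log$cases)
  if (total == 0) stopf("completion_rate(): no cases")
  completers <- log$appointments |>
    filter(!is.na(attended), is_treatment, attended) |>
    count(case_id) |>
    filter(n >= 2) |>
    pull(case_id)
  out <- ratio_pct(length(completers), total)
  out$completers <- completers
  out
}

#' Recovery rate among treatment completers
#'
#' Recovery requires being at or above the caseness threshold at the
#' first treatment session and below it at the last. The denominator is
#' completers with outcome data who started at caseness; completers
#' without outcome data and those below caseness at the start are
#' reported separately, together with the outcome data-completeness
#' fraction among completers.
#'
#' @param log A `careflow_log`.
#' @param completers Character vector of completer case ids; defaults to
#'   [completion_rate()]'s.
#' @return A list with `numerator`, `denominator`, `pct` (or `NA` when the
#'   denominator is 0), `n_no_data`, `n_below_caseness_at_start`, and
#'   `data_completeness` (a `ratio_pct` list).
#' @export
recovery_rate <- function(log, completers = NULL) {
  stopifnot(inherits(log, "careflow_log"))
  if (is.null(completers)) completers <- completion_rate(log)$completers
  oc <- log$outcomes |>
    filter(case_id %in% completers) |>
    arrange(case_id, session_index) |>
    group_by(case_id) |>
    summarise(first_above = dplyr::first(above_caseness),
              last_below = !dplyr::last(above_caseness), .groups = "drop")
  n_completers <- length(completers)
  n_with_data <- nrow(oc)
  at_caseness <- oc |> filter(first_above)
  recovered <- sum(at_caseness$last_below)
  denom <- nrow(at_caseness)
  list(
    numerator = recovered,
    denominator = denom,
    pct = if (denom == 0) NA_real_ else round(100 * recovered / denom, 2),
    n_no_data = n_completers - n_with_data,
    n_below_caseness_at_start = n_with_data - denom,
    data_completeness = if (n_completers == 0) NULL else
      ratio_pct(n_with_data, n_completers)
  )
}

#' Missed appointment rate
#'
#' Proportion of all scheduled appointments (with a known attendance
#' flag) that were not attended.
#'
#' @param log A `careflow_log`.
#' @return A `ratio_pct` list (2 dp).
#' @export
missed_appointment_rate <- function(log) {
  stopifnot(inherits(log, "careflow_log"))
  ap <- log$appointments |> filter(!is.na(attended))
  if (nrow(ap) == 0) stopf("missed_appointment_rate(): no scheduled appointments")
  ratio_pct(sum(!ap$attended), nrow(ap))
}

#' Patient-flow breakdown from an annotated process map
#'
#' Recomputes the headline flow percentages of the process map: the share
#' of referrals discharged immediately, the share of assessed patients
#' discharged after assessment (also as a share of all mapped referrals),
#' and pre-treatment waiting-list attrition per step, over triaged
#' patients and over all mapped referrals. Edge counts are distinct-case
#' counts. Stages are located through `stage_roles`; rows whose stages
#' are absent from the map are omitted and listed in `notes`.
#'
#' @param map A `process_map` (semantic annotation not required).
#' @param stage_roles Named character vector, stage -> role.
#' @return A list with `table` (tibble: measure, numerator, denominator,
#'   pct at 2 dp) and `notes`.
#' @export
flow_breakdown <- function(map, stage_roles = default_stage_roles()) {
  stopifnot(inherits(map, "process_map"))
  role_of <- function(stage) unname(stage_roles[stage])
  stages_for <- function(role) names(stage_roles)[stage_roles == role]
  node_count <- function(role) {
    acts <- intersect(stages_for(role), map$nodes$activity)
    if (length(acts) == 0) return(NA_integer_)
    sum(map$nodes$n_cases[map$nodes$activity %in% acts])
  }
  edge_count <- function(from_role, to_role) {
    e <- map$edges
    hit <- role_of(e$from) %in% from_role & role_of(e$to) %in% to_role
    if (!any(hit)) return(0L)
    sum(e$n_cases[hit])
  }
  total <- map$total_cases
  notes <- character()
  rows <- list()
  push <- function(measure, num, den) {
    if (is.na(den) || den == 0) {
      notes <<- c(notes, sprintf("%s: denominator unavailable", measure))
      return()
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      measure = measure, numerator = num, denominator = den,
      pct = round(100 * num / den, 2))
  }

  push("immediate_discharge_of_all",
       edge_count("referral", "discharge"), total)
  assessed <- node_count("assessment")
  post_assess <- edge_count("assessment", "discharge")
  push("post_assessment_discharge_of_assessed", post_assess, assessed)
  push("post_assessment_discharge_of_all", post_assess, total)
  n2 <- node_count("step2_waitlist"); n3 <- node_count("step3_waitlist")
  a2 <- edge_count("step2_waitlist", "discharge")
  a3 <- edge_count("step3_waitlist", "discharge")
  triaged <- if (is.na(n2) && is.na(n3)) NA_integer_ else
    sum(c(n2, n3), na.rm = TRUE)
  push("pre_treatment_attrition_of_triaged", a2 + a3, triaged)
  push("pre_treatment_attrition_of_all", a2 + a3, total)
  push("pre_treatment_attrition_step2_of_step2", a2, n2)
  push("pre_treatment_attrition_step3_of_step3", a3, n3)

  list(table = dplyr::bind_rows(rows), notes = notes)
}

#' Coverage fraction retained by variant filtering
#'
#' @param retained,total Case counts, `retained <= total`.
#' @return A `ratio_pct` list (2 dp).
#' @export
coverage_fraction <- function(retained, total) {
  if (total == 0) stopf("coverage_fraction(): total is zero")
  if (retained > total) stopf("coverage_fraction(): retained exceeds total")
  ratio_pct(retained, total)
}

#' Share of events adjusted by timestamp repair
#'
#' @param report An `imputation_report` from [impute_timestamps()].
#' @return A `ratio_pct` list at 1 dp.
#' @export
imputation_rate <- function(report) {
  stopifnot(inherits(report, "imputation_report"))
  if (report$n_events_total == 0) stopf("imputation_rate(): no events")
  ratio_pct(report$n_events_adjusted, report$n_events_total, dp = 1)
}

#' Cohort summary in the style of a service data-summary table
#'
#' Assembles referral counts, the performance rates, deprivation-decile
#' proportions over cases with a known decile, demographic proportion
#' tables, and mean/SD/median/IQR summaries of referral duration, total
#' waiting time and treatment-session counts (all referrals and
#' completers).
#'
#' @param log A `careflow_log`.
#' @param stage_roles Named character vector used to identify
#'   waiting-list stages for the total-wait summary.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(log, stage_roles = default_stage_roles()) {
  stopifnot(inherits(log, "careflow_log"))
  comp <- completion_rate(log)
  rec <- recovery_rate(log, comp$completers)
  missed <- missed_appointment_rate(log)

  cs <- log$cases
  decile <- NULL
  if ("imd_decile" %in% names(cs)) {
    known <- cs$imd_decile[!is.na(cs$imd_decile)]
    decile <- as.numeric(table(factor(known, levels = 1:10)) / length(known))
  }
  cat_table <- function(col) {
    if (!col %in% names(cs)) return(NULL)
    cs |> count(.data[[col]], name = "n") |>
      mutate(pct = round(100 * n / sum(n), 2))
  }

  dur <- case_stage_durations(log, stage_roles)
  per_case <- dur |>
    group_by(case_id) |>
    summarise(referral_weeks = weeks_between(max(timestamp), min(timestamp)),
              wait_weeks = sum(duration_weeks[is_wait], na.rm = TRUE),
              .groups = "drop")
  sessions <- log$appointments |>
    filter(is_treatment) |>
    count(case_id, name = "n_sessions")
  n_sess_all <- tibble::tibble(case_id = cs$case_id) |>
    left_join(sessions, by = "case_id") |>
    mutate(n_sessions = ifelse(is.na(n_sessions), 0L, n_sessions))

  structure(list(
    n_referrals = nrow(cs),
    completion = comp[c("numerator", "denominator", "pct")],
    recovery = rec,
    missed_appointments = missed,
    deprivation_decile_proportions = decile,
    demographics = list(
      gender = cat_table("gender"),
      presenting_problem = cat_table("presenting_problem"),
      referral_source = cat_table("referral_source")
    ),
    waits = list(
      referral_duration_weeks = mean_sd_med_iqr(per_case$referral_weeks),
      total_waiting_weeks = mean_sd_med_iqr(per_case$wait_weeks),
      sessions_all = mean_sd_med_iqr(n_sess_all$n_sessions),
      sessions_completers = mean_sd_med_iqr(
        n_sess_all$n_sessions[n_sess_all$case_id %in% comp$completers])
    )
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  referrals: %d\n", x$n_referrals))
  cat(sprintf("  completion rate: %d/%d (%.2f%%)\n",
              x$completion$numerator, x$completion$denominator,
              x$completion$pct))
  if (!is.na(x$recovery$pct)) {
    cat(sprintf("  recovery rate:   %d/%d (%.2f%%)\n",
                x$recovery$numerator, x$recovery$denominator, x$recovery$pct))
  }
  cat(sprintf("  missed appts:    %d/%d (%.2f%%)\n",
              x$missed_appointments$numerator,
              x$missed_appointments$denominator, x$missed_appointments$pct))
  w <- x$waits$total_waiting_weeks
  cat(sprintf("  total wait (wk): mean %.1f (SD %.1f); median %.1f (IQR %.1f-%.1f)\n",
              w$mean, w$sd, w$median, w$q1, w$q3))
  invisible(x)
}
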