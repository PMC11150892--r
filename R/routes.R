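# Common-route (trace variant) analysis: enumeration, ranking, per-route
# timing and outcome statistics, classification, and plot data.

ROUTE_CLASSES <- c("no_treatment", "step2_only", "step3_only", "stepped_care",
                   "attrition_step2_wl", "attrition_step3_wl",
                   "attrition_assessment_wl", "other")

classify_one_route <- function(stages, stage_roles) {
  roles <- unname(stage_roles[stages])
  roles[is.na(roles)] <- "other"
  i2 <- match("step2_treatment", roles)
  i3 <- match("step3_treatment", roles)
  if (!is.na(i2) && !is.na(i3) && i2 < i3) return("stepped_care")
  if ("step3_waitlist" %in% roles && is.na(i3)) return("attrition_step3_wl")
  if ("step2_waitlist" %in% roles && is.na(i2)) return("attrition_step2_wl")
  if ("assessment_waitlist" %in% roles && !"assessment" %in% roles) {
    return("attrition_assessment_wl")
  }
  if (!is.na(i2)) return("step2_only")
  if (!is.na(i3)) return("step3_only")
  if (is.na(i2) && is.na(i3)) return("no_treatment")
  "other"
}

#' Classify route strings into pathway classes
#'
#' Classes form a partition: `stepped_care` (step-2 treatment followed by
#' step-3 treatment), waiting-list attrition classes (a waiting list was
#' joined but its assessment/treatment never followed, checked from step 3
#' down), `step2_only` / `step3_only`, `no_treatment` and `other`.
#'
#' @param routes Character vector of `" -> "`-joined stage sequences.
#' @param stage_roles Named character vector, stage -> role (see
#'   [default_stage_roles()]).
#' @return Character vector of route classes, same length as `routes`.
#' @export
classify_route_strings <- function(routes, stage_roles = default_stage_roles()) {
  uniq <- unique(routes)
  cls <- vapply(strsplit(uniq, " -> ", fixed = TRUE),
                classify_one_route, character(1), stage_roles = stage_roles)
  unname(setNames(cls, uniq)[routes])
}

case_outcome_bins <- function(log) {
  completers <- log$appointments |>
    filter(is_treatment, attended) |>
    count(case_id) |>
    filter(n >= 2) |>
    pull(case_id)
  oc <- log$outcomes |>
    arrange(case_id, session_index) |>
    group_by(case_id) |>
    summarise(first_above = dplyr::first(above_caseness),
              last_below = !dplyr::last(above_caseness), .groups = "drop")
  tibble::tibble(case_id = log$cases$case_id) |>
    mutate(completed = case_id %in% completers) |>
    left_join(oc, by = "case_id") |>
    mutate(has_outcome = !is.na(first_above),
           outcome_bin = dplyr::case_when(
             completed & has_outcome & first_above & last_below ~ "recovered",
             completed & has_outcome & first_above & !last_below ~ "not_recovered",
             completed & has_outcome & !first_above ~ "not_at_caseness",
             TRUE ~ "unknown"
           ))
}

case_stage_durations <- function(log, stage_roles) {
  log$events |>
    arrange(case_id, source_order) |>
    group_by(case_id) |>
    mutate(position = row_number(),
           duration_weeks = weeks_between(dplyr::lead(timestamp), timestamp)) |>
    ungroup() |>
    mutate(is_wait = unname(stage_roles[activity]) %in%
             c("assessment_waitlist", "step2_waitlist", "step3_waitlist"))
}

#' Enumerate and summarise pathway routes
#'
#' One summary per distinct full stage sequence, ranked by descending case
#' count (ties broken lexicographically by route string). Per-route
#' statistics: per-stage-position median durations, the median over the
#' route's cases of each case's total time on waiting-list stages
#' (`total_wait_median_weeks`, a median of per-case sums), and the
#' referral-outcome proportions `rate_recovered`, `rate_not_recovered`
#' (completed but still at caseness), `rate_not_at_caseness` (below the
#' caseness threshold at treatment start), `rate_unknown` (did not
#' complete treatment, or no outcome data) — these four partition each
#' route's cases and sum to 1 — plus `pct_completed`.
#'
#' Intended for a level-B style log in which waiting-list stages are
#' retained; on a log without waiting stages the total-wait medians are 0.
#'
#' @param log A `careflow_log`.
#' @param stage_roles Named character vector, stage -> role.
#' @return A tibble of class `route_summaries`, one row per route, with a
#'   `case_stats` attribute (per-case route, total wait and outcome bin)
#'   used by [top_n_with_other()].
#' @export
enumerate_routes <- function(log, stage_roles = default_stage_roles()) {
  stopifnot(inherits(log, "careflow_log"))
  dur <- case_stage_durations(log, stage_roles)
  per_case <- dur |>
    group_by(case_id) |>
    summarise(route = route_string(activity),
              total_wait_weeks = sum(duration_weeks[is_wait], na.rm = TRUE),
              .groups = "drop") |>
    left_join(case_outcome_bins(log) |>
                select(case_id, completed, outcome_bin),
              by = "case_id")
  total <- nrow(per_case)

  stage_meds <- dur |>
    left_join(per_case |> select(case_id, route), by = "case_id") |>
    group_by(route, position) |>
    summarise(activity = dplyr::first(activity),
              stage_median = if (all(is.na(duration_weeks))) 0 else
                q_lin(duration_weeks[!is.na(duration_weeks)], 0.5),
              .groups = "drop")

  summaries <- per_case |>
    group_by(route) |>
    summarise(
      n_cases = dplyr::n(),
      total_wait_median_weeks = q_lin(total_wait_weeks, 0.5),
      pct_completed = mean(completed),
      rate_recovered = mean(outcome_bin == "recovered"),
      rate_not_recovered = mean(outcome_bin == "not_recovered"),
      rate_not_at_caseness = mean(outcome_bin == "not_at_caseness"),
      rate_unknown = mean(outcome_bin == "unknown"),
      .groups = "drop"
    ) |>
    mutate(pct_of_all = 100 * n_cases / total,
           route_class = classify_route_strings(route, stage_roles)) |>
    arrange(desc(n_cases), route) |>
    mutate(rank = row_number())

  meds <- stage_meds |>
    group_by(route) |>
    summarise(stage_medians_weeks = list(setNames(stage_median, activity)),
              .groups = "drop")
  summaries <- summaries |>
    left_join(meds, by = "route") |>
    select(rank, route, route_class, n_cases, pct_of_all,
           total_wait_median_weeks, stage_medians_weeks, pct_completed,
           rate_recovered, rate_not_recovered, rate_not_at_caseness,
           rate_unknown)
  attr(summaries, "case_stats") <- per_case
  attr(summaries, "total_cases") <- total
  class(summaries) <- c("route_summaries", class(summaries))
  summaries
}

#' Top-N routes plus a pooled "other" aggregate
#'
#' Returns the `n` highest-ranked route summaries and one aggregate row
#' pooling all remaining cases: outcome proportions recomputed over the
#' pooled cases and the total-wait median taken over the pooled cases
#' (not averaged across routes).
#'
#' @param summaries A `route_summaries` from [enumerate_routes()].
#' @param n Number of top routes (default 10).
#' @return A list with `top` (tibble) and `other` (one-row tibble; 0 cases
#'   when every route is in the top `n`).
#' @export
top_n_with_other <- function(summaries, n = 10) {
  if (n < 1) stopf("top_n_with_other(): n must be >= 1")
  top <- summaries |> filter(rank <= n)
  rest_routes <- summaries$route[summaries$rank > n]
  cs <- attr(summaries, "case_stats")
  total <- attr(summaries, "total_cases")
  rest <- cs |> filter(route %in% rest_routes)
  other <- tibble::tibble(
    rank = NA_integer_, route = "(other routes)", route_class = "other",
    n_cases = nrow(rest),
    pct_of_all = 100 * nrow(rest) / total,
    total_wait_median_weeks = if (nrow(rest) == 0) NA_real_ else
      q_lin(rest$total_wait_weeks, 0.5),
    stage_medians_weeks = list(numeric()),
    pct_completed = if (nrow(rest) == 0) NA_real_ else mean(rest$completed),
    rate_recovered = if (nrow(rest) == 0) NA_real_ else
      mean(rest$outcome_bin == "recovered"),
    rate_not_recovered = if (nrow(rest) == 0) NA_real_ else
      mean(rest$outcome_bin == "not_recovered"),
    rate_not_at_caseness = if (nrow(rest) == 0) NA_real_ else
      mean(rest$outcome_bin == "not_at_caseness"),
    rate_unknown = if (nrow(rest) == 0) NA_real_ else
      mean(rest$outcome_bin == "unknown")
  )
  list(top = top, other = other)
}

#' Stepped-care rate breakdown
#'
#' Decomposes the stepped-care rate into cases on common (top-`top_n`)
#' stepped-care routes and cases stepped up through less common routes,
#' and reports their sum as a percentage of all cases (2 dp). Counts can
#' be supplied directly via `common` / `uncommon` instead of `summaries`
#' (worked-example mode).
#'
#' @param summaries A `route_summaries`, or `NULL` when counts are given.
#' @param total_cases Total number of referrals.
#' @param top_n Rank cut-off defining "common" routes (default 10).
#' @param common,uncommon Optional direct counts of stepped-care cases on
#'   common and uncommon routes.
#' @return A list with `common`, `uncommon`, `total_stepped`, `pct`.
#' @export
stepped_care_rate <- function(summaries = NULL, total_cases, top_n = 10,
                              common = NULL, uncommon = NULL) {
  if (total_cases == 0) stopf("stepped_care_rate(): total_cases is zero")
  if (is.null(common)) {
    stepped <- summaries |> filter(route_class == "stepped_care")
    common <- sum(stepped$n_cases[stepped$rank <= top_n])
    uncommon <- sum(stepped$n_cases[stepped$rank > top_n])
  }
  total_stepped <- common + uncommon
  list(common = common, uncommon = uncommon, total_stepped = total_stepped,
       pct = round(100 * total_stepped / total_cases, 2))
}

#' Compare treated-route waits with their attrition counterparts
#'
#' For each step level, pairs the total-wait median of the most common
#' treated route (`step2_only` / `step3_only`) with the most common
#' waiting-list-attrition counterpart (`attrition_step2_wl` /
#' `attrition_step3_wl`) and reports the difference in weeks (1 dp). Also
#' reports the ratio of the step-3 to the step-2 treated-route medians
#' (1 dp). Missing counterparts are omitted with a note.
#'
#' @param summaries A `route_summaries`.
#' @return A list with `pairs` (tibble: step, treated and attrition
#'   medians, difference), `step3_vs_step2_ratio` and `notes`.
#' @export
wait_comparison <- function(summaries) {
  pick <- function(cls) {
    sub <- summaries |> filter(route_class == cls) |> arrange(rank)
    if (nrow(sub) == 0) NA_real_ else sub$total_wait_median_weeks[1]
  }
  notes <- character()
  rows <- list()
  for (step in c("step2", "step3")) {
    treated <- pick(paste0(step, "_only"))
    attr_m <- pick(paste0("attrition_", step, "_wl"))
    if (is.na(treated) || is.na(attr_m)) {
      notes <- c(notes, sprintf("%s: treated/attrition pair incomplete, omitted", step))
      next
    }
    rows[[step]] <- tibble::tibble(
      step = step,
      treated_median_weeks = treated,
      attrition_median_weeks = attr_m,
      difference_weeks = round(attr_m - treated, 1)
    )
  }
  t2 <- pick("step2_only"); t3 <- pick("step3_only")
  ratio <- if (is.na(t2) || is.na(t3) || t2 == 0) {
    notes <- c(notes, "step3-vs-step2 treated ratio unavailable")
    NA_real_
  } else round(t3 / t2, 1)
  list(pairs = dplyr::bind_rows(rows), step3_vs_step2_ratio = ratio,
       notes = notes)
}

#' Tabular specification of the common-route timeline chart
#'
#' One row per route and stage position: `offset_weeks` is the cumulative
#' sum of the preceding stage medians, `width_weeks` the stage's own
#' median duration, alongside the route's outcome proportions — enough to
#' render a stacked-timeline chart of the common routes. The pooled
#' "other" aggregate, when given, is appended as a single full-width row.
#'
#' @param top Tibble of top routes (from [top_n_with_other()]).
#' @param other Optional one-row "other" aggregate.
#' @return A tibble ordered by rank then stage position.
#' @export
export_route_plot_data <- function(top, other = NULL) {
  rows <- purrr::pmap(
    list(top$rank, top$route, top$stage_medians_weeks),
    function(rk, rt, meds) {
      stages <- strsplit(rt, " -> ", fixed = TRUE)[[1]]
      w <- as.numeric(meds)
      w[is.na(w)] <- 0
      tibble::tibble(rank = rk, route = rt, position = seq_along(stages),
                     stage = stages,
                     offset_weeks = cumsum(c(0, head(w, -1))),
                     width_weeks = w)
    }
  )
  out <- dplyr::bind_rows(rows) |>
    left_join(top |>
                select(rank, n_cases, pct_of_all, rate_recovered,
                       rate_not_recovered, rate_not_at_caseness, rate_unknown),
              by = "rank")
  if (!is.null(other) && other$n_cases > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      rank = max(top$rank) + 1L, route = other$route, position = 1L,
      stage = other$route, offset_weeks = 0,
      width_weeks = other$total_wait_median_weeks,
      n_cases = other$n_cases, pct_of_all = other$pct_of_all,
      rate_recovered = other$rate_recovered,
      rate_not_recovered = other$rate_not_recovered,
      rate_not_at_caseness = other$rate_not_at_caseness,
      rate_unknown = other$rate_unknown
    ))
  }
  out |> arrange(rank, position)
}

#' Plot the common-route timelines
#'
#' Renders the output of [export_route_plot_data()] as a stacked timeline:
#' one horizontal bar per route, segmented by stage, widths equal to the
#' per-stage median durations.
#'
#' @param plot_data Tibble from [export_route_plot_data()].
#' @return A `ggplot` object.
#' @export
plot_routes <- function(plot_data) {
  plot_data$route_lab <- stats::reorder(
    paste0(plot_data$route, "\n(n=", plot_data$n_cases, ")"), -plot_data$rank)
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(xmin = offset_weeks,
                               xmax = offset_weeks + width_weeks,
                               y = route_lab, fill = stage)) +
    ggplot2::geom_rect(ggplot2::aes(ymin = as.numeric(route_lab) - 0.4,
                                    ymax = as.numeric(route_lab) + 0.4)) +
    ggplot2::labs(x = "median duration (weeks)", y = NULL, fill = "stage") +
    ggplot2::theme_minimal()
}
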