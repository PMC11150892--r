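# End-to-end pipeline: simulate a synthetic site to CSV, and run the full
# analysis (repair -> abstraction -> process map -> routes -> cohort
# report) over an event-log directory. A thin command-line wrapper around
# these functions ships in inst/cli/careflow.R.

#' Build a pipeline run configuration
#'
#' @param input_dir Directory of event-log CSVs (for [cmd_analyze()]).
#' @param profile A [site_profile()], packaged profile name, or YAML path
#'   (for [cmd_simulate()]).
#' @param out_dir Output directory (created if needed).
#' @param coverage Variant-coverage fraction for the process map
#'   (default 0.95).
#' @param bottleneck_percentile Quantile for bottleneck flagging
#'   (default 0.99).
#' @param top_n Number of common routes to report (default 10).
#' @param stage_roles Stage -> role map for semantics, route
#'   classification and flow breakdown.
#' @param n_cases,seed Optional overrides for simulation.
#' @param verbose Log per-stage counts with `message()`.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, profile = "site_a", out_dir,
                       coverage = 0.95, bottleneck_percentile = 0.99,
                       top_n = 10, stage_roles = default_stage_roles(),
                       n_cases = NULL, seed = NULL, verbose = TRUE) {
  if (coverage <= 0 || coverage > 1) {
    stopf("run_config(): coverage must be in (0, 1]")
  }
  if (top_n < 1) stopf("run_config(): top_n must be >= 1")
  structure(list(input_dir = input_dir, profile = profile, out_dir = out_dir,
                 coverage = coverage,
                 bottleneck_percentile = bottleneck_percentile,
                 top_n = top_n, stage_roles = stage_roles,
                 n_cases = n_cases, seed = seed, verbose = verbose),
            class = "run_config")
}

resolve_profile <- function(config) {
  p <- config$profile
  if (inherits(p, "site_profile")) {
    if (!is.null(config$n_cases)) p$n_cases <- config$n_cases
    if (!is.null(config$seed)) p$seed <- as.integer(config$seed)
    return(validate_profile(p))
  }
  if (is.character(p) && p %in% c("site_a", "site_b")) {
    return(packaged_profile(p, n_cases = config$n_cases, seed = config$seed))
  }
  if (is.character(p) && file.exists(p)) {
    prof <- read_site_profile(p)
    if (!is.null(config$n_cases)) prof$n_cases <- config$n_cases
    if (!is.null(config$seed)) prof$seed <- as.integer(config$seed)
    return(validate_profile(prof))
  }
  stopf("cmd_simulate(): cannot resolve profile '%s'", as.character(p))
}

#' Simulate a synthetic site and write its event log to CSV
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  profile <- resolve_profile(config)
  log <- generate_log(profile)
  if (isTRUE(config$verbose)) {
    message(sprintf("simulate: %d cases, %d events -> %s",
                    n_cases(log), nrow(log$events), config$out_dir))
  }
  write_log(log, config$out_dir)
  invisible(config$out_dir)
}

say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline over an event-log directory
#'
#' Stages: read -> timestamp repair (LOCF) -> abstraction level A with
#' coverage filtering -> directly-follows process map with bottleneck
#' scoring, semantic annotation and flow breakdown -> abstraction level B
#' (full coverage) -> route enumeration, top-N summary, stepped-care rate
#' and wait comparison -> cohort summary. All outputs are written to
#' `config$out_dir`; the run is deterministic given its inputs.
#'
#' @param config A [run_config()] with `input_dir` set.
#' @return Invisibly, a list with the main in-memory results (`map`,
#'   `routes`, `cohort`, `imputation_report`, paths of written files).
#' @export
cmd_analyze <- function(config) {
  if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
    stopf("cmd_analyze(): input_dir does not exist")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  log <- read_log(config$input_dir)
  if (nrow(log$events) == 0) stopf("cmd_analyze(): event log is empty")
  lr <- load_report(log)
  say(config, "read: %d cases, %d events (%d rows rejected)",
      n_cases(log), nrow(log$events), lr$n_rejected)

  rep <- impute_timestamps(log)
  say(config, "impute: %d/%d events adjusted",
      rep$report$n_events_adjusted, rep$report$n_events_total)
  imp_json <- file.path(out, "imputation_report.json")
  jsonlite::write_json(list(
    n_events_total = rep$report$n_events_total,
    n_events_adjusted = rep$report$n_events_adjusted,
    n_cases_total = rep$report$n_cases_total,
    n_cases_adjusted = rep$report$n_cases_adjusted,
    pct_adjusted = imputation_rate(rep$report)$pct,
    summary = rep$report$summary
  ), imp_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # process map on abstraction level A
  absA <- apply_abstraction(rep$log, packaged_abstraction("A"),
                            coverage = config$coverage)
  say(config, "abstraction A: %d cases retained", absA$n_retained)
  readr::write_csv(absA$summary, file.path(out, "abstraction_summary_A.csv"))
  map <- mine_dfg(absA$log, coverage_used = config$coverage) |>
    score_bottlenecks(config$bottleneck_percentile) |>
    annotate_semantics(config$stage_roles)
  export_dot(map, file.path(out, "process_map.dot"))
  process_map_json(map, file.path(out, "process_map.json"))
  fb <- flow_breakdown(map, config$stage_roles)
  readr::write_csv(fb$table, file.path(out, "flow_breakdown.csv"))
  say(config, "process map: %d stages, %d flows", nrow(map$nodes),
      nrow(map$edges))

  # route analysis on abstraction level B at full coverage
  absB <- apply_abstraction(rep$log, packaged_abstraction("B"), coverage = 1)
  readr::write_csv(absB$summary, file.path(out, "abstraction_summary_B.csv"))
  routes <- enumerate_routes(absB$log, config$stage_roles)
  tno <- top_n_with_other(routes, config$top_n)
  scr <- stepped_care_rate(routes, total_cases = n_cases(absB$log),
                           top_n = config$top_n)
  wc <- wait_comparison(routes)
  say(config, "routes: %d variants, stepped care %.2f%%", nrow(routes),
      scr$pct)
  flatten_routes <- function(df) {
    df$stage_medians_weeks <- vapply(
      df$stage_medians_weeks, function(m) paste(round(m, 1), collapse = ";"),
      character(1))
    df
  }
  readr::write_csv(flatten_routes(routes), file.path(out, "route_summaries.csv"))
  if (nrow(wc$pairs) > 0) {
    readr::write_csv(wc$pairs, file.path(out, "wait_comparison.csv"))
  }
  pd <- export_route_plot_data(tno$top, tno$other)
  readr::write_csv(pd, file.path(out, "route_plot_data.csv"))

  cohort <- cohort_summary(absB$log, config$stage_roles)
  jsonlite::write_json(
    list(n_referrals = cohort$n_referrals, completion = cohort$completion,
         recovery = cohort$recovery[c("numerator", "denominator", "pct")],
         missed_appointments = cohort$missed_appointments,
         stepped_care = scr, waits = cohort$waits),
    file.path(out, "cohort_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(map = map, routes = routes, top = tno, cohort = cohort,
                 stepped_care = scr, wait_comparison = wc,
                 imputation_report = rep$report, flow_breakdown = fb,
                 out_dir = out))
}
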