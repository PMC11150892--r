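# Event-log data model, CSV readers/writers, and timestamp repair.
#
# An event log is the central container of the package: one row per recorded
# movement of a referral (a "case") into a pathway stage, together with
# per-case attributes, appointment records and session outcome scores.

EVENT_COLS <- c("case_id", "activity", "timestamp", "source_order",
                "imputed", "original_timestamp")

#' Construct a care-pathway event log
#'
#' Bundles the four tables the pipeline consumes: pathway movements
#' (`events`), per-case attributes (`cases`), appointment records
#' (`appointments`) and session outcome scores (`outcomes`).
#'
#' @param events Data frame with columns `case_id` (character), `activity`
#'   (character, the stage label) and `timestamp` (`POSIXct`). Optional
#'   columns `source_order`, `imputed`, `original_timestamp` are filled in
#'   when absent: `source_order` numbers events within each case in input
#'   order and is treated as the authoritative sequence.
#' @param cases Data frame with one row per case (`case_id` plus attribute
#'   columns such as `age`, `gender`, `presenting_problem`,
#'   `referral_source`, `imd_decile`, `prior_referrals`). Defaults to the
#'   distinct case ids of `events`.
#' @param appointments Data frame with columns `case_id`, `datetime`,
#'   `attended` (logical), `is_treatment` (logical); may be empty.
#' @param outcomes Data frame with columns `case_id`, `session_index`,
#'   `score`, `above_caseness` (logical); may be empty.
#' @param validate Run structural validation (default `TRUE`).
#' @return An object of class `careflow_log`.
#' @export
event_log <- function(events, cases = NULL, appointments = NULL,
                      outcomes = NULL, validate = TRUE) {
  events <- tibble::as_tibble(events)
  req <- c("case_id", "activity", "timestamp")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    stopf("event_log(): events is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  events$case_id <- as.character(events$case_id)
  events$activity <- as.character(events$activity)
  if (!inherits(events$timestamp, "POSIXct")) {
    stopf("event_log(): events$timestamp must be POSIXct")
  }
  if (!"source_order" %in% names(events)) {
    events <- events |>
      group_by(case_id) |>
      mutate(source_order = row_number()) |>
      ungroup()
  }
  events$source_order <- as.integer(events$source_order)
  if (!"imputed" %in% names(events)) events$imputed <- FALSE
  if (!"original_timestamp" %in% names(events)) {
    events$original_timestamp <- as.POSIXct(NA, tz = "UTC")
  }
  events <- events |>
    select(all_of(EVENT_COLS), everything()) |>
    arrange(case_id, source_order)

  if (is.null(cases)) {
    cases <- tibble::tibble(case_id = unique(events$case_id))
  } else {
    cases <- tibble::as_tibble(cases)
    cases$case_id <- as.character(cases$case_id)
  }
  appointments <- empty_or_tibble(appointments, c("case_id", "datetime",
                                                  "attended", "is_treatment"))
  outcomes <- empty_or_tibble(outcomes, c("case_id", "session_index",
                                          "score", "above_caseness"))

  log <- structure(
    list(events = events, cases = cases,
         appointments = appointments, outcomes = outcomes),
    class = "careflow_log"
  )
  if (validate) validate_log(log)
  log
}

empty_or_tibble <- function(x, cols) {
  if (is.null(x)) {
    proto <- list(
      case_id = character(), datetime = as.POSIXct(character(), tz = "UTC"),
      attended = logical(), is_treatment = logical(),
      session_index = integer(), score = double(), above_caseness = logical()
    )
    return(tibble::as_tibble(proto[cols]))
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stopf("event_log(): table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x$case_id <- as.character(x$case_id)
  x
}

#' Validate the structural invariants of an event log
#'
#' Checks that `source_order` is unique and contiguous within each case,
#' that every event's case appears in the case table, and that the
#' `imputed` flag agrees with `original_timestamp`.
#'
#' @param log A `careflow_log`.
#' @return `log`, invisibly; errors describe the first violated invariant.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "careflow_log"))
  ev <- log$events
  bad_order <- ev |>
    group_by(case_id) |>
    summarise(ok = identical(sort(source_order), seq_along(source_order)),
              .groups = "drop") |>
    filter(!ok)
  if (nrow(bad_order) > 0) {
    stopf("validate_log(): source_order not unique/contiguous for case(s): %s",
          paste(head(bad_order$case_id, 3), collapse = ", "))
  }
  orphan <- setdiff(unique(ev$case_id), log$cases$case_id)
  if (length(orphan) > 0) {
    stopf("validate_log(): events reference unknown case(s): %s",
          paste(head(orphan, 3), collapse = ", "))
  }
  bad_imp <- ev$imputed & (is.na(ev$original_timestamp) |
                             ev$original_timestamp == ev$timestamp)
  bad_imp2 <- !ev$imputed & !is.na(ev$original_timestamp)
  if (any(bad_imp) || any(bad_imp2)) {
    stopf("validate_log(): imputed flag inconsistent with original_timestamp")
  }
  invisible(log)
}

#' @export
print.careflow_log <- function(x, ...) {
  cat("<careflow_log>\n")
  cat(sprintf("  cases:        %d\n", nrow(x$cases)))
  cat(sprintf("  events:       %d over %d distinct stages\n",
              nrow(x$events), dplyr::n_distinct(x$events$activity)))
  cat(sprintf("  appointments: %d\n", nrow(x$appointments)))
  cat(sprintf("  outcomes:     %d\n", nrow(x$outcomes)))
  invisible(x)
}

#' Number of cases in an event log
#' @param log A `careflow_log`.
#' @return Integer count of cases.
#' @export
n_cases <- function(log) nrow(log$cases)

# ---------------------------------------------------------------------------
# Readers / writers

LOG_FILES <- c(events = "movements.csv", cases = "cases.csv",
               appointments = "appointments.csv", outcomes = "outcomes.csv")

#' Read an event log from delimited text files
#'
#' Expects `movements.csv` (required) and optionally `cases.csv`,
#' `appointments.csv`, `outcomes.csv` in `dir`, comma-separated with a
#' header row, timestamps as ISO-8601 datetimes (parsed timezone-naive as
#' UTC). Movement rows with a missing `case_id` or an unparseable
#' `timestamp` are rejected and counted in the load report, available via
#' [load_report()].
#'
#' @param dir Directory containing the CSV tables.
#' @return A `careflow_log` with a `load_report` attribute.
#' @export
read_log <- function(dir) {
  path <- file.path(dir, LOG_FILES[["events"]])
  if (!file.exists(path)) stopf("read_log(): %s not found", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("case_id", "activity", "timestamp")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stopf("read_log(): movements.csv missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  ts <- parse_iso_datetime(raw$timestamp)
  bad_case <- is.na(raw$case_id) | raw$case_id == ""
  bad_ts <- is.na(ts)
  keep <- !bad_case & !bad_ts
  report <- list(
    n_rows = nrow(raw),
    n_rejected = sum(!keep),
    n_missing_case_id = sum(bad_case),
    n_bad_timestamp = sum(bad_ts & !bad_case)
  )
  events <- tibble::tibble(
    case_id = raw$case_id[keep],
    activity = raw$activity[keep],
    timestamp = ts[keep]
  )
  if ("source_order" %in% names(raw)) {
    events$source_order <- as.integer(raw$source_order[keep])
  }
  if ("imputed" %in% names(raw)) {
    events$imputed <- as.logical(raw$imputed[keep])
    events$original_timestamp <- parse_iso_datetime(raw$original_timestamp[keep])
  }

  cases <- read_side_table(dir, "cases")
  appts <- read_side_table(dir, "appointments")
  if (!is.null(appts) && is.character(appts$datetime)) {
    appts$datetime <- parse_iso_datetime(appts$datetime)
  }
  outcomes <- read_side_table(dir, "outcomes")

  log <- event_log(events, cases, appts, outcomes)
  attr(log, "load_report") <- report
  log
}

# column types are guessed (ISO datetimes -> POSIXct, TRUE/FALSE ->
# logical) except case_id, which is always opaque text
read_side_table <- function(dir, name) {
  path <- file.path(dir, LOG_FILES[[name]])
  if (!file.exists(path)) return(NULL)
  readr::read_csv(path,
                  col_types = readr::cols(case_id = readr::col_character(),
                                          .default = readr::col_guess()),
                  progress = FALSE)
}

# tolerant ISO-8601 parsing: unparseable strings become NA rather than
# erroring, so the caller can reject and count them
parse_iso_datetime <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

format_iso <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

#' Write an event log to delimited text files
#'
#' Writes `movements.csv`, `cases.csv`, `appointments.csv`, `outcomes.csv`
#' into `dir` (created if needed). The round trip
#' `read_log(write_log(log, dir))` is lossless for the documented columns,
#' including imputation provenance (`imputed`, `original_timestamp`).
#'
#' @param log A `careflow_log`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_log <- function(log, dir) {
  stopifnot(inherits(log, "careflow_log"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- log$events
  ev$timestamp <- format_iso(ev$timestamp)
  ev$original_timestamp <- format_iso(ev$original_timestamp)
  readr::write_csv(ev, file.path(dir, LOG_FILES[["events"]]))
  readr::write_csv(log$cases, file.path(dir, LOG_FILES[["cases"]]))
  ap <- log$appointments
  ap$datetime <- format_iso(ap$datetime)
  readr::write_csv(ap, file.path(dir, LOG_FILES[["appointments"]]))
  readr::write_csv(log$outcomes, file.path(dir, LOG_FILES[["outcomes"]]))
  invisible(dir)
}

#' Retrieve the load report attached by `read_log()`
#' @param log A `careflow_log` returned by [read_log()].
#' @return A list with `n_rows`, `n_rejected`, `n_missing_case_id`,
#'   `n_bad_timestamp`, or `NULL` if the log was not read from disk.
#' @export
load_report <- function(log) attr(log, "load_report")

#' Export an event log as minimal XES XML
#'
#' Writes a minimal XES-compatible document (one `<trace>` per case, one
#' `<event>` per movement with `concept:name` and `time:timestamp`
#' attributes) for interoperability with standard process-mining tools.
#'
#' @param log A `careflow_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xes <- function(log, path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stopf("write_xes() requires the xml2 package")
  }
  doc <- xml2::xml_new_root("log", "xes.version" = "1.0")
  ev <- log$events |> arrange(case_id, source_order)
  for (cid in unique(ev$case_id)) {
    trace <- xml2::xml_add_child(doc, "trace")
    xml2::xml_add_child(trace, "string", key = "concept:name", value = cid)
    sub <- ev[ev$case_id == cid, ]
    for (i in seq_len(nrow(sub))) {
      e <- xml2::xml_add_child(trace, "event")
      xml2::xml_add_child(e, "string", key = "concept:name",
                          value = sub$activity[i])
      xml2::xml_add_child(e, "date", key = "time:timestamp",
                          value = format_iso(sub$timestamp[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Timestamp repair

#' Detect out-of-order timestamps
#'
#' The recorded entry order (`source_order`) is treated as the true event
#' sequence; an event is flagged when its timestamp precedes the maximum
#' timestamp among earlier events of the same case.
#'
#' @param log A `careflow_log`.
#' @return Tibble of violating events (possibly empty) with the running
#'   maximum they violate (`running_max`).
#' @export
detect_order_violations <- function(log) {
  stopifnot(inherits(log, "careflow_log"))
  log$events |>
    arrange(case_id, source_order) |>
    group_by(case_id) |>
    mutate(running_max = as.POSIXct(cummax_posix(timestamp),
                                    origin = "1970-01-01", tz = "UTC"),
           prior_max = dplyr::lag(running_max)) |>
    ungroup() |>
    filter(!is.na(prior_max) & timestamp < prior_max) |>
    select(case_id, activity, timestamp, source_order,
           running_max = prior_max)
}

cummax_posix <- function(ts) cummax(as.numeric(ts))

#' Repair out-of-order timestamps by last observation carried forward
#'
#' Every event whose timestamp precedes the running maximum of the repaired
#' timestamps earlier in its case is replaced by that running maximum
#' (LOCF), so repaired per-case timestamps are non-decreasing in
#' `source_order`. Repaired events carry `imputed = TRUE` and retain the
#' recorded value in `original_timestamp`. The accompanying report
#' summarises adjustment sizes (|new - old| in weeks) per event and per
#' case, over all units and over adjusted units only.
#'
#' @param log A `careflow_log`.
#' @param strategy Repair strategy; only `"locf"` is implemented.
#' @return A list with elements `log` (repaired `careflow_log`) and
#'   `report` (an `imputation_report`).
#' @export
impute_timestamps <- function(log, strategy = "locf") {
  stopifnot(inherits(log, "careflow_log"))
  strategy <- match.arg(strategy, "locf")
  ev <- log$events |> arrange(case_id, source_order)
  num <- as.numeric(ev$timestamp)
  runmax <- ave(num, ev$case_id, FUN = cummax)
  adjusted <- num < runmax
  new_ts <- as.POSIXct(runmax, origin = "1970-01-01", tz = "UTC")

  out <- ev
  out$original_timestamp[adjusted] <- ev$timestamp[adjusted]
  out$timestamp <- new_ts
  out$imputed <- out$imputed | adjusted

  adj_weeks <- (runmax - num) / WEEK_SECONDS  # zero where unadjusted
  per_case <- tibble::tibble(case_id = ev$case_id, adj = adj_weeks) |>
    group_by(case_id) |>
    summarise(total_weeks = sum(adj), n_adjust = sum(adj > 0), .groups = "drop")
  # cases in the case table but with no events still count as unadjusted
  all_case_ids <- log$cases$case_id
  per_case <- tibble::tibble(case_id = all_case_ids) |>
    left_join(per_case, by = "case_id") |>
    mutate(total_weeks = ifelse(is.na(total_weeks), 0, total_weeks),
           n_adjust = ifelse(is.na(n_adjust), 0L, as.integer(n_adjust)))

  report <- new_imputation_report(
    adj_weeks = adj_weeks,
    per_case = per_case,
    n_events_total = nrow(ev)
  )
  repaired <- log
  repaired$events <- out
  list(log = repaired, report = report)
}

new_imputation_report <- function(adj_weeks, per_case, n_events_total) {
  adjusted_case <- per_case$n_adjust > 0
  summary <- dplyr::bind_rows(
    "adjustment_per_event_all" = mean_sd_med_iqr(adj_weeks),
    "adjustment_per_event_adjusted" = mean_sd_med_iqr(adj_weeks[adj_weeks > 0]),
    "total_per_case_all" = mean_sd_med_iqr(per_case$total_weeks),
    "total_per_case_adjusted" = mean_sd_med_iqr(per_case$total_weeks[adjusted_case]),
    "count_per_case_all" = mean_sd_med_iqr(as.numeric(per_case$n_adjust)),
    "count_per_case_adjusted" = mean_sd_med_iqr(as.numeric(per_case$n_adjust[adjusted_case])),
    .id = "statistic"
  )
  structure(
    list(
      n_events_total = n_events_total,
      n_events_adjusted = sum(adj_weeks > 0),
      n_cases_total = nrow(per_case),
      n_cases_adjusted = sum(adjusted_case),
      adjustment_sizes_weeks = adj_weeks,
      per_case_totals_weeks = per_case$total_weeks,
      per_case_counts = per_case$n_adjust,
      summary = summary
    ),
    class = "imputation_report"
  )
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("<imputation_report>\n")
  cat(sprintf("  events adjusted: %d / %d (%.1f%%)\n",
              x$n_events_adjusted, x$n_events_total,
              100 * x$n_events_adjusted / max(1, x$n_events_total)))
  cat(sprintf("  cases adjusted:  %d / %d\n",
              x$n_cases_adjusted, x$n_cases_total))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-32s mean %.1f (SD %.1f); median %.1f (IQR %.1f-%.1f)\n",
                s$statistic[i], s$mean[i], s$sd[i], s$median[i], s$q1[i], s$q3[i]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Case filtering

#' Filter cases by attribute predicates
#'
#' Keeps exactly the cases whose row in the case table satisfies every
#' predicate, with all their events, appointments and outcomes.
#'
#' @param log A `careflow_log`.
#' @param ... Logical expressions over case-attribute columns, as in
#'   [dplyr::filter()] (e.g. `age >= 18`).
#' @return The filtered `careflow_log`.
#' @export
filter_cases <- function(log, ...) {
  stopifnot(inherits(log, "careflow_log"))
  kept <- log$cases |> filter(...)
  ids <- kept$case_id
  out <- log
  out$cases <- kept
  out$events <- log$events |> filter(case_id %in% ids)
  out$appointments <- log$appointments |> filter(case_id %in% ids)
  out$outcomes <- log$outcomes |> filter(case_id %in% ids)
  out
}
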