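# Event-log abstraction: stage renaming, subprocess collapsing,
# administrative-stage exclusion, and variant-coverage filtering.
#
# Raw pathway configurations accumulate near-duplicate stage labels and
# administrative events; abstraction produces simplified views of the log
# at two conventional levels: level A (rename, collapse, drop waiting-list
# and administrative stages) for process mapping, and level B (rename,
# collapse treatments into step-level subprocesses, keep waiting lists)
# for route analysis.

#' Define an abstraction specification
#'
#' @param name Level label, `"A"` or `"B"` (free-form labels accepted).
#' @param rename_map Named character vector, raw stage label -> canonical
#'   label.
#' @param subprocess_groups Named list; each element is the set of
#'   canonical stage labels collapsed into the subprocess named by the
#'   element. No label may belong to two groups.
#' @param exclusions Character vector of stage labels removed from the log
#'   (applied after collapsing, so they must be disjoint from the
#'   subprocess output labels).
#' @return An `abstraction_spec`.
#' @export
abstraction_spec <- function(name, rename_map = character(),
                             subprocess_groups = list(),
                             exclusions = character()) {
  members <- unlist(subprocess_groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stopf("abstraction_spec(): label(s) mapped into two subprocess groups: %s",
          paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  clash <- intersect(exclusions, names(subprocess_groups))
  if (length(clash) > 0) {
    stopf("abstraction_spec(): exclusions overlap subprocess outputs: %s",
          paste(clash, collapse = ", "))
  }
  structure(list(name = name, rename_map = rename_map,
                 subprocess_groups = subprocess_groups,
                 exclusions = exclusions),
            class = "abstraction_spec")
}

#' Read an abstraction spec from YAML
#' @param path YAML file with keys `name`, `rename_map`,
#'   `subprocess_groups`, `exclusions`.
#' @return An `abstraction_spec`.
#' @export
read_abstraction_spec <- function(path) {
  y <- yaml::read_yaml(path)
  abstraction_spec(
    name = y$name,
    rename_map = unlist(y$rename_map) %||% character(),
    subprocess_groups = lapply(y$subprocess_groups %||% list(), unlist),
    exclusions = unlist(y$exclusions) %||% character()
  )
}

#' Load a packaged abstraction level for the synthetic stage vocabulary
#'
#' Level `"A"` renames legacy labels, collapses the discharge-planning /
#' discharged pair, and excludes waiting-list stages. Level `"B"`
#' additionally collapses individual therapies into `step2_treatment` /
#' `step3_treatment` subprocesses and keeps the waiting-list stages, which
#' route analysis relies on.
#'
#' @param level `"A"` or `"B"`.
#' @return An `abstraction_spec`.
#' @export
packaged_abstraction <- function(level = c("A", "B")) {
  level <- match.arg(level)
  path <- system.file("extdata", "abstraction",
                      paste0("level_", tolower(level), ".yaml"),
                      package = "careflow")
  read_abstraction_spec(path)
}

#' Rename stage labels
#'
#' Replaces each activity by its image under `spec$rename_map` (identity
#' where absent). Event count is unchanged.
#'
#' @param log A `careflow_log`.
#' @param spec An [abstraction_spec()].
#' @return The renamed `careflow_log`.
#' @export
remap_stages <- function(log, spec) {
  stopifnot(inherits(log, "careflow_log"))
  rm_ <- spec$rename_map
  if (length(rm_) == 0) return(log)
  hit <- log$events$activity %in% names(rm_)
  log$events$activity[hit] <- unname(rm_[log$events$activity[hit]])
  log
}

#' Collapse consecutive same-subprocess events
#'
#' Each maximal run of consecutive events (in `source_order`) whose
#' activities belong to one subprocess group is replaced by a single event
#' labelled with the subprocess name and carrying the run's first
#' timestamp. Events outside every group are untouched. Idempotent.
#'
#' @param log A `careflow_log`.
#' @param spec An [abstraction_spec()].
#' @return The collapsed `careflow_log`.
#' @export
collapse_subprocesses <- function(log, spec) {
  stopifnot(inherits(log, "careflow_log"))
  groups <- spec$subprocess_groups
  if (length(groups) == 0) return(log)
  membership <- setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  # the subprocess label itself belongs to its group, making the
  # operation idempotent
  self <- setNames(names(groups), names(groups))
  membership <- c(membership, self[!names(self) %in% names(membership)])

  ev <- log$events |> arrange(case_id, source_order)
  grp <- unname(membership[ev$activity])  # NA outside every group
  new_case <- !duplicated(ev$case_id)
  prev_grp <- dplyr::lag(grp)
  same_run <- !new_case & !is.na(grp) & !is.na(prev_grp) & grp == prev_grp
  keep <- !same_run
  out <- ev[keep, ]
  gi <- which(!is.na(grp[keep]))
  out$activity[gi] <- grp[keep][gi]
  out <- out |>
    group_by(case_id) |>
    mutate(source_order = row_number()) |>
    ungroup()
  log$events <- out
  log
}

#' Exclude administrative stages
#'
#' Removes all events whose activity is in `spec$exclusions`. Cases left
#' with no events are dropped from the case table; the count of dropped
#' cases is attached as attribute `n_cases_dropped`.
#'
#' @param log A `careflow_log`.
#' @param spec An [abstraction_spec()].
#' @return The filtered `careflow_log`.
#' @export
exclude_stages <- function(log, spec) {
  stopifnot(inherits(log, "careflow_log"))
  if (length(spec$exclusions) == 0) {
    attr(log, "n_cases_dropped") <- 0L
    return(log)
  }
  ev <- log$events |>
    filter(!activity %in% spec$exclusions) |>
    group_by(case_id) |>
    mutate(source_order = row_number()) |>
    ungroup()
  surviving <- unique(ev$case_id)
  dropped <- setdiff(log$cases$case_id, surviving)
  out <- log
  out$events <- ev
  out$cases <- log$cases |> filter(case_id %in% surviving)
  out$appointments <- log$appointments |> filter(case_id %in% surviving)
  out$outcomes <- log$outcomes |> filter(case_id %in% surviving)
  attr(out, "n_cases_dropped") <- length(dropped)
  out
}

case_routes <- function(log) {
  log$events |>
    arrange(case_id, source_order) |>
    group_by(case_id) |>
    summarise(route = route_string(activity), .groups = "drop")
}

#' Filter a log to its most common routes
#'
#' Ranks distinct routes (full stage sequences) by descending case count
#' (ties broken lexicographically by route string), then retains routes in
#' rank order until the cumulative retained-case fraction reaches
#' `coverage`, including the route that crosses the threshold.
#'
#' @param log A `careflow_log`.
#' @param coverage Fraction in `(0, 1]` of cases to retain.
#' @return A list with `log` (restricted to retained cases), `n_retained`
#'   (case count) and `routes_kept` (number of route variants retained).
#' @export
filter_by_coverage <- function(log, coverage) {
  stopifnot(inherits(log, "careflow_log"))
  if (coverage <= 0 || coverage > 1) {
    stopf("filter_by_coverage(): coverage must be in (0, 1]")
  }
  cr <- case_routes(log)
  total <- nrow(cr)
  ranked <- cr |>
    count(route, name = "n_cases") |>
    arrange(desc(n_cases), route)
  cum_frac <- cumsum(ranked$n_cases) / total
  k <- which(cum_frac >= coverage - 1e-12)[1]
  kept_routes <- ranked$route[seq_len(k)]
  kept_ids <- cr$case_id[cr$route %in% kept_routes]
  out <- log
  out$cases <- log$cases |> filter(case_id %in% kept_ids)
  out$events <- log$events |> filter(case_id %in% kept_ids)
  out$appointments <- log$appointments |> filter(case_id %in% kept_ids)
  out$outcomes <- log$outcomes |> filter(case_id %in% kept_ids)
  list(log = out, n_retained = length(kept_ids), routes_kept = k)
}

#' Apply a full abstraction level
#'
#' Composes the abstraction steps in the fixed order rename -> collapse ->
#' exclude -> coverage filter, and reports the distinct-stage and
#' distinct-route counts before and after (the abstraction summary).
#'
#' @param log A `careflow_log`.
#' @param spec An [abstraction_spec()].
#' @param coverage Coverage fraction passed to [filter_by_coverage()]
#'   (default 1 = keep everything).
#' @return A list with `log` (the abstracted log), `summary` (a tibble of
#'   stage/route counts per step) and `n_retained`.
#' @export
apply_abstraction <- function(log, spec, coverage = 1) {
  count_log <- function(lg) {
    tibble::tibble(n_stages = dplyr::n_distinct(lg$events$activity),
                   n_routes = dplyr::n_distinct(case_routes(lg)$route),
                   n_cases = nrow(lg$cases))
  }
  steps <- list(raw = log)
  steps$renamed <- remap_stages(steps$raw, spec)
  steps$collapsed <- collapse_subprocesses(steps$renamed, spec)
  steps$excluded <- exclude_stages(steps$collapsed, spec)
  cov <- filter_by_coverage(steps$excluded, coverage)
  steps$covered <- cov$log
  summary <- dplyr::bind_rows(lapply(steps, count_log), .id = "step")
  list(log = steps$covered, summary = summary, n_retained = cov$n_retained)
}
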