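# Directly-follows process maps: mining, performance annotation,
# bottleneck scoring and DOT export.

#' Mine a directly-follows process map from an event log
#'
#' Edge `(a, b)` counts the consecutive event pairs "a then b" (by
#' `source_order`) over all cases; each traversal contributes a transition
#' duration `timestamp(b) - timestamp(a)` in weeks. A node's stage
#' duration is the time from entering the stage to the next event of the
#' case (terminal events contribute none). Branching probabilities divide
#' each edge's traversal count by the total outgoing traversals of its
#' source node. Medians and IQRs use linear-interpolation quantiles.
#'
#' @param log A `careflow_log` with non-decreasing per-case timestamps.
#' @param coverage_used Optional coverage fraction recorded on the map for
#'   provenance.
#' @return A `process_map` with tibbles `nodes` (`activity`, `n_cases`,
#'   `n_traversals`, `n_starts`, `n_ends`, duration stats) and `edges`
#'   (`from`, `to`, `n_traversals`, `n_cases`, `probability`, duration
#'   stats), plus `total_cases`.
#' @export
mine_dfg <- function(log, coverage_used = NA_real_) {
  stopifnot(inherits(log, "careflow_log"))
  ev <- log$events |> arrange(case_id, source_order)
  if (nrow(ev) == 0) {
    return(new_process_map(empty_nodes(), empty_edges(), 0L, coverage_used))
  }
  ev <- ev |>
    group_by(case_id) |>
    mutate(next_activity = dplyr::lead(activity),
           duration_weeks = weeks_between(dplyr::lead(timestamp), timestamp)) |>
    ungroup()

  nodes <- ev |>
    group_by(activity) |>
    summarise(
      n_cases = dplyr::n_distinct(case_id),
      n_traversals = dplyr::n(),
      n_starts = sum(source_order == 1L),
      n_ends = sum(is.na(next_activity)),
      median_weeks = if (all(is.na(duration_weeks))) NA_real_ else
        q_lin(duration_weeks[!is.na(duration_weeks)], 0.5),
      q1_weeks = if (all(is.na(duration_weeks))) NA_real_ else
        q_lin(duration_weeks[!is.na(duration_weeks)], 0.25),
      q3_weeks = if (all(is.na(duration_weeks))) NA_real_ else
        q_lin(duration_weeks[!is.na(duration_weeks)], 0.75),
      .groups = "drop"
    ) |>
    arrange(activity)

  pairs <- ev |> filter(!is.na(next_activity))
  edges <- pairs |>
    group_by(from = activity, to = next_activity) |>
    summarise(
      n_traversals = dplyr::n(),
      n_cases = dplyr::n_distinct(case_id),
      median_weeks = q_lin(duration_weeks, 0.5),
      q1_weeks = q_lin(duration_weeks, 0.25),
      q3_weeks = q_lin(duration_weeks, 0.75),
      .groups = "drop"
    ) |>
    group_by(from) |>
    mutate(probability = n_traversals / sum(n_traversals)) |>
    ungroup() |>
    arrange(from, to)

  new_process_map(nodes, edges, dplyr::n_distinct(ev$case_id), coverage_used)
}

empty_nodes <- function() {
  tibble::tibble(activity = character(), n_cases = integer(),
                 n_traversals = integer(), n_starts = integer(),
                 n_ends = integer(), median_weeks = double(),
                 q1_weeks = double(), q3_weeks = double())
}

empty_edges <- function() {
  tibble::tibble(from = character(), to = character(),
                 n_traversals = integer(), n_cases = integer(),
                 median_weeks = double(), q1_weeks = double(),
                 q3_weeks = double(), probability = double())
}

new_process_map <- function(nodes, edges, total_cases, coverage_used) {
  structure(list(nodes = nodes, edges = edges,
                 total_cases = total_cases, coverage_used = coverage_used),
            class = "process_map")
}

#' @export
print.process_map <- function(x, ...) {
  cat("<process_map>\n")
  cat(sprintf("  stages: %d, flows: %d, cases: %d\n",
              nrow(x$nodes), nrow(x$edges), x$total_cases))
  if (!is.na(x$coverage_used)) {
    cat(sprintf("  coverage: %.2f\n", x$coverage_used))
  }
  if ("bottleneck" %in% names(x$edges) && any(x$edges$bottleneck)) {
    b <- x$edges |> filter(bottleneck)
    cat(sprintf("  bottleneck flow(s): %s\n",
                paste(paste0(b$from, " -> ", b$to), collapse = "; ")))
  }
  invisible(x)
}

#' Score and flag bottleneck flows
#'
#' The bottleneck indicator of an edge is the product of the number of
#' patients who moved between the two stages (distinct cases) and the
#' median transition duration in weeks. Edges whose score is at or above
#' the given quantile of all edge scores are flagged.
#'
#' @param map A `process_map`.
#' @param percentile Quantile in `(0, 1)` above which edges are flagged
#'   (default 0.99, i.e. the highest percentile).
#' @return The map with `bottleneck_score` and `bottleneck` edge columns.
#' @export
score_bottlenecks <- function(map, percentile = 0.99) {
  stopifnot(inherits(map, "process_map"))
  if (percentile <= 0 || percentile >= 1) {
    stopf("score_bottlenecks(): percentile must be in (0, 1)")
  }
  edges <- map$edges
  edges$bottleneck_score <- edges$n_cases * edges$median_weeks
  if (nrow(edges) == 0) {
    edges$bottleneck <- logical(0)
  } else {
    cut <- q_lin(edges$bottleneck_score, percentile)
    edges$bottleneck <- edges$bottleneck_score >= cut &
      edges$bottleneck_score > 0
  }
  map$edges <- edges
  map
}

#' Default stage roles for the synthetic vocabulary
#'
#' Maps each canonical (level-B) stage label to its pathway role, used by
#' [annotate_semantics()] and route classification.
#'
#' @return Named character vector, stage -> role.
#' @export
default_stage_roles <- function() {
  c(referral_received = "referral",
    assessment_wl = "assessment_waitlist",
    assessment = "assessment",
    step2_wl = "step2_waitlist",
    step2_treatment = "step2_treatment",
    step3_wl = "step3_waitlist",
    step3_treatment = "step3_treatment",
    # individual therapy stages, present in level-A style logs
    gsh = "step2_treatment", ccbt = "step2_treatment",
    cbt = "step3_treatment", counselling = "step3_treatment",
    emdr = "step3_treatment",
    discharge_planning = "discharge",
    discharged = "discharge")
}

STAGE_ROLES <- c("referral", "assessment_waitlist", "assessment",
                 "step2_waitlist", "step2_treatment", "step3_waitlist",
                 "step3_treatment", "discharge", "other")

#' Mark attrition and step-up flows
#'
#' Marks edges from a waiting-list stage to a discharge stage as
#' waiting-list attrition (patients discharged before receiving the
#' intended assessment or treatment), and edges from step-2 stages into
#' step-3 stages as step-up.
#'
#' @param map A `process_map`.
#' @param stage_roles Named character vector, stage label -> role; roles
#'   must be one of `careflow:::STAGE_ROLES`. Defaults to
#'   [default_stage_roles()].
#' @return The map with logical edge columns `is_attrition`, `is_step_up`.
#' @export
annotate_semantics <- function(map, stage_roles = default_stage_roles()) {
  stopifnot(inherits(map, "process_map"))
  stages <- unique(c(map$edges$from, map$edges$to, map$nodes$activity))
  unknown <- setdiff(stages, names(stage_roles))
  if (length(unknown) > 0) {
    stopf("annotate_semantics(): no role for stage(s): %s",
          paste(unknown, collapse = ", "))
  }
  bad <- setdiff(unique(stage_roles), STAGE_ROLES)
  if (length(bad) > 0) {
    stopf("annotate_semantics(): unknown stage role(s): %s",
          paste(bad, collapse = ", "))
  }
  from_role <- unname(stage_roles[map$edges$from])
  to_role <- unname(stage_roles[map$edges$to])
  map$edges$is_attrition <- grepl("waitlist$", from_role) &
    to_role == "discharge"
  map$edges$is_step_up <- from_role %in% c("step2_waitlist", "step2_treatment") &
    to_role %in% c("step3_waitlist", "step3_treatment")
  map
}

#' Export a process map to DOT
#'
#' Renders the map as a Graphviz digraph: node labels carry the case count
#' and median stage duration, edge labels the traversal count, branching
#' probability and median wait; bottleneck-flagged edges are coloured red
#' and attrition / step-up flows are styled when present. Output ordering
#' is deterministic (alphabetical).
#'
#' @param map A `process_map`.
#' @param path Optional file to write the DOT text to.
#' @param bottleneck_color Edge colour for flagged bottlenecks.
#' @return The DOT source as a character scalar (invisibly when `path`
#'   is given).
#' @export
export_dot <- function(map, path = NULL, bottleneck_color = "red") {
  stopifnot(inherits(map, "process_map"))
  nd <- map$nodes |> arrange(activity)
  ed <- map$edges |> arrange(from, to)
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  node_lines <- if (nrow(nd) == 0) character() else sprintf(
    '  %s [label="%s\\ncases: %d%s", shape=box];',
    q(nd$activity), nd$activity, nd$n_cases,
    ifelse(is.na(nd$median_weeks), "",
           sprintf("\\nmedian %.1f wk", nd$median_weeks))
  )
  edge_lines <- if (nrow(ed) == 0) character() else {
    style <- rep("", nrow(ed))
    if ("bottleneck" %in% names(ed)) {
      style <- ifelse(ed$bottleneck,
                      sprintf(", color=%s, penwidth=2", bottleneck_color), "")
    }
    marker <- rep("", nrow(ed))
    if ("is_attrition" %in% names(ed)) {
      marker <- ifelse(ed$is_attrition, " [attrition]",
                       ifelse(ed$is_step_up, " [step-up]", ""))
    }
    sprintf('  %s -> %s [label="n=%d (%.1f%%)\\nmedian %.1f wk%s"%s];',
            q(ed$from), q(ed$to), ed$n_traversals, 100 * ed$probability,
            ed$median_weeks, marker, style)
  }
  dot <- paste(c("digraph process_map {", "  rankdir=TB;",
                 node_lines, edge_lines, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

#' Serialise a process map to JSON
#'
#' @param map A `process_map`.
#' @param path Optional output file.
#' @return JSON text (invisibly when `path` is given).
#' @export
process_map_json <- function(map, path = NULL) {
  obj <- list(total_cases = map$total_cases,
              coverage_used = map$coverage_used,
              nodes = map$nodes, edges = map$edges)
  js <- jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
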