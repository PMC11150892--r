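# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code; the larger ones are cached per session.

the_cache <- new.env(parent = emptyenv())

# standard 5000-case site_a log used by the statistical recovery tests
std_site_a_log <- function() {
  if (is.null(the_cache$site_a)) {
    the_cache$site_a <- generate_log(
      packaged_profile("site_a", n_cases = 5000, seed = 424242))
  }
  the_cache$site_a
}

std_repaired <- function() {
  if (is.null(the_cache$repaired)) {
    the_cache$repaired <- impute_timestamps(std_site_a_log())
  }
  the_cache$repaired
}

std_level_b <- function() {
  if (is.null(the_cache$level_b)) {
    the_cache$level_b <- apply_abstraction(std_repaired()$log,
                                           packaged_abstraction("B"),
                                           coverage = 1)
  }
  the_cache$level_b
}

# build a log from traces given as named numeric vectors:
# names = activities, values = week offsets from the case start
log_from_traces <- function(traces, start = "2020-01-06") {
  t0 <- as.POSIXct(start, tz = "UTC")
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(case_id = sprintf("c%02d", i),
               activity = names(tr),
               timestamp = t0 + unname(tr) * 7 * 86400)
  })
  event_log(do.call(rbind, rows))
}

# independent directly-follows oracle: plain base-R pair counting
oracle_dfg_counts <- function(log) {
  ev <- log$events[order(log$events$case_id, log$events$source_order), ]
  acc <- list()
  for (cid in unique(ev$case_id)) {
    a <- ev$activity[ev$case_id == cid]
    if (length(a) < 2) next
    for (j in seq_len(length(a) - 1)) {
      key <- paste0(a[j], "\r", a[j + 1])
      acc[[key]] <- (acc[[key]] %||% 0L) + 1L
    }
  }
  if (length(acc) == 0) {
    return(data.frame(from = character(), to = character(), n = integer()))
  }
  parts <- strsplit(names(acc), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    n = unlist(acc, use.names = FALSE))
  out[order(out$from, out$to), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small log over at most `n_stages` stages; optional fixed
# source/sink stages for flow-conservation properties
random_small_log <- function(n_cases = 10, n_stages = 8,
                             source_sink = FALSE) {
  alphabet <- LETTERS[seq_len(n_stages)]
  traces <- lapply(seq_len(sample(2:n_cases, 1)), function(i) {
    len <- sample(2:6, 1)
    mid <- sample(alphabet, len, replace = TRUE)
    acts <- if (source_sink) c("START", mid, "END") else mid
    offs <- cumsum(c(0, round(runif(length(acts) - 1, 0, 4), 2)))
    stats::setNames(offs, acts)
  })
  log_from_traces(traces)
}

# theoretical probability of a canonical route under a profile's routing,
# multiplied out decision by decision (closed-form oracle)
route_probability <- function(profile, route) {
  stages <- strsplit(route, " -> ", fixed = TRUE)[[1]]
  r <- profile$routing
  p <- 1
  nxt_after <- function(s) stages[match(s, stages) + 1]
  if (!"assessment_wl" %in% stages) return(r$post_referral[["discharge"]])
  p <- p * r$post_referral[["proceed"]]
  if (!"assessment" %in% stages) return(p * r$assessment_waitlist[["discharge"]])
  p <- p * r$assessment_waitlist[["proceed"]]
  if (!"step2_wl" %in% stages && !"step3_wl" %in% stages) {
    return(p * r$post_assessment[["discharge"]])
  }
  if ("step2_wl" %in% stages) {
    p <- p * r$post_assessment[["step2"]]
    if (!"step2_treatment" %in% stages) return(p * r$step2_waitlist[["discharge"]])
    p <- p * r$step2_waitlist[["proceed"]]
    if (!"step3_wl" %in% stages) return(p * r$step2_treatment[["discharge"]])
    p <- p * r$step2_treatment[["step_up"]]
    if (!"step3_treatment" %in% stages) return(p * r$step3_waitlist[["discharge"]])
    return(p * r$step3_waitlist[["proceed"]])
  }
  p <- p * r$post_assessment[["step3"]]
  if (!"step3_treatment" %in% stages) return(p * r$step3_waitlist[["discharge"]])
  p * r$step3_waitlist[["proceed"]]
}

binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
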