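# Seeded synthetic stepped-care event-log generator.
#
# Emulates the structure of an NHS Talking Therapies style service:
# referral -> assessment waiting list -> assessment -> triage to step-2 or
# step-3 waiting lists -> treatment (with possible step-up from 2 to 3) ->
# discharge, with waiting-list attrition, appointment attendance, pre/post
# outcome scores and a controlled rate of back-dated timestamps. Ground
# truth (routes, recovery, uncorrupted timestamps) is recorded so every
# downstream stage can be tested against known answers.

# -- distribution specs -----------------------------------------------------

#' Waiting-time / magnitude distribution specification
#'
#' A small declarative spec used throughout the generator. Supported
#' families: `"lognormal"` (`location` = meanlog, `scale` = sdlog; the
#' sugar keys `median` + `sdlog` set `location = log(median)`),
#' `"exponential"` (`scale` = mean), `"uniform"` (`location` to
#' `location + scale`) and `"fixed"` (`location`). Units are weeks.
#'
#' @param family Distribution family name.
#' @param location,scale Family parameters (see above).
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(family, location = 0, scale = 1) {
  family <- match.arg(family, c("lognormal", "exponential", "uniform", "fixed"))
  structure(list(family = family, location = location, scale = scale),
            class = "dist_spec")
}

parse_dist <- function(x, field = "wait_dists") {
  if (inherits(x, "dist_spec")) return(x)
  if (!is.list(x) || is.null(x$family)) {
    stopf("site_profile(): %s entry is not a distribution spec", field)
  }
  if (!is.null(x$median)) {
    x$location <- log(x$median)
    if (is.null(x$scale)) x$scale <- x$sdlog %||% 0.6
  }
  dist_spec(x$family, x$location %||% 0, x$scale %||% 1)
}

draw_dist <- function(spec, n) {
  switch(spec$family,
    lognormal = rlnorm(n, meanlog = spec$location, sdlog = spec$scale),
    exponential = stats::rexp(n, rate = 1 / spec$scale),
    uniform = runif(n, spec$location, spec$location + spec$scale),
    fixed = rep(spec$location, n)
  )
}

#' Median of a distribution spec (weeks)
#' @param spec A `dist_spec`.
#' @return The theoretical median.
#' @export
dist_median <- function(spec) {
  switch(spec$family,
    lognormal = exp(spec$location),
    exponential = spec$scale * log(2),
    uniform = spec$location + spec$scale / 2,
    fixed = spec$location
  )
}

draw_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# -- site profile -----------------------------------------------------------

ROUTING_POINTS <- c("post_referral", "assessment_waitlist", "post_assessment",
                    "step2_waitlist", "step2_treatment", "step3_waitlist",
                    "step3_treatment")

WAIT_TRANSITIONS <- c(
  "post_referral_discharge", "referral_to_assessment_wl",
  "assessment_wl_to_assessment", "assessment_wl_to_discharge",
  "assessment_to_triage", "post_assessment_discharge",
  "step2_wl_to_treatment", "step2_wl_to_discharge",
  "step3_wl_to_treatment", "step3_wl_to_discharge",
  "step_up_gap", "treatment_to_discharge",
  "discharge_planning_to_discharged", "therapy_switch_gap"
)

#' Define a synthetic site profile
#'
#' A `site_profile` fixes every parameter of the generator: routing
#' probabilities at each decision point, waiting-time distributions per
#' transition, the session model, attendance behaviour, the outcome model,
#' and the timestamp-corruption process. Two packaged fixture profiles
#' (`"site_a"`, `"site_b"`) are available via [packaged_profile()].
#'
#' @param site_name Label used as the case-id prefix.
#' @param n_cases Number of referrals to simulate.
#' @param routing Named list of named probability vectors, one per decision
#'   point: `post_referral` (`proceed`/`discharge`), `assessment_waitlist`
#'   (`proceed`/`discharge`), `post_assessment`
#'   (`step2`/`step3`/`discharge`), `step2_waitlist`, `step3_waitlist`
#'   (`proceed`/`discharge`), `step2_treatment` (`discharge`/`step_up`),
#'   `step3_treatment` (`discharge`). Each vector must sum to 1.
#' @param wait_dists Named list of [dist_spec()]s (weeks), one per
#'   transition; see `careflow:::WAIT_TRANSITIONS` for the required names.
#' @param session_model List with `n_sessions` (a `dist_spec`; the draw is
#'   `1 + round(draw)` so every episode has at least one session) and `gap`
#'   (inter-session gap `dist_spec`, weeks).
#' @param attendance_prob Probability a scheduled treatment session is
#'   attended.
#' @param outcome_model List with `pre_mean`, `pre_sd` (initial score
#'   distribution), `caseness_threshold`, and `p_recover`, a named vector
#'   of recovery probabilities by route class (`step2_only`, `step3_only`,
#'   `stepped_care`, `other`).
#' @param corruption_rate Probability each non-first event's timestamp is
#'   back-dated.
#' @param corruption_magnitude `dist_spec` of back-dating offsets (weeks).
#' @param therapy_mix List with `step2` and `step3` named probability
#'   vectors over therapy stage labels.
#' @param switch_prob Named vector: probability of a second consecutive
#'   therapy stage within an episode, per step.
#' @param legacy_label_prob Probability selected stages are emitted under a
#'   legacy label variant (exercises the rename step of abstraction).
#' @param window_start Start of the referral inclusion window
#'   (ISO date string or `POSIXct`).
#' @param window_weeks Width of the window referral timestamps are drawn
#'   uniformly over (default 104, a 2-year window).
#' @param seed Integer seed; identical profiles give byte-identical logs.
#' @return A validated `site_profile` object.
#' @export
site_profile <- function(site_name, n_cases, routing, wait_dists,
                         session_model, attendance_prob, outcome_model,
                         corruption_rate = 0, corruption_magnitude = dist_spec("lognormal", log(2), 1),
                         therapy_mix = default_therapy_mix(),
                         switch_prob = c(step2 = 0.25, step3 = 0.15),
                         legacy_label_prob = 0.15,
                         window_start = "2019-06-01", window_weeks = 104,
                         seed = 1L) {
  wait_dists <- lapply(wait_dists, parse_dist)
  session_model$n_sessions <- parse_dist(session_model$n_sessions, "session_model")
  session_model$gap <- parse_dist(session_model$gap, "session_model")
  corruption_magnitude <- parse_dist(corruption_magnitude, "corruption_magnitude")
  profile <- structure(
    list(site_name = site_name, n_cases = n_cases, routing = routing,
         wait_dists = wait_dists, session_model = session_model,
         attendance_prob = attendance_prob, outcome_model = outcome_model,
         corruption_rate = corruption_rate,
         corruption_magnitude = corruption_magnitude,
         therapy_mix = therapy_mix, switch_prob = switch_prob,
         legacy_label_prob = legacy_label_prob,
         window_start = as.POSIXct(window_start, tz = "UTC"),
         window_weeks = window_weeks, seed = as.integer(seed)),
    class = "site_profile"
  )
  validate_profile(profile)
}

default_therapy_mix <- function() {
  list(step2 = c(gsh = 0.7, ccbt = 0.3),
       step3 = c(cbt = 0.6, counselling = 0.3, emdr = 0.1))
}

validate_profile <- function(p) {
  if (!is.numeric(p$n_cases) || p$n_cases < 1 || p$n_cases != round(p$n_cases)) {
    stopf("site_profile(): n_cases must be a positive integer")
  }
  missing_pts <- setdiff(ROUTING_POINTS, names(p$routing))
  if (length(missing_pts) > 0) {
    stopf("site_profile(): routing is missing decision point(s): %s",
          paste(missing_pts, collapse = ", "))
  }
  for (pt in ROUTING_POINTS) {
    v <- p$routing[[pt]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stopf("site_profile(): routing$%s probabilities must be non-negative and sum to 1", pt)
    }
  }
  missing_w <- setdiff(WAIT_TRANSITIONS, names(p$wait_dists))
  if (length(missing_w) > 0) {
    stopf("site_profile(): wait_dists is missing transition(s): %s",
          paste(missing_w, collapse = ", "))
  }
  for (nm in names(p$wait_dists)) {
    if (p$wait_dists[[nm]]$scale <= 0 && p$wait_dists[[nm]]$family != "fixed") {
      stopf("site_profile(): wait_dists$%s scale must be strictly positive", nm)
    }
  }
  if (p$corruption_rate < 0 || p$corruption_rate > 1) {
    stopf("site_profile(): corruption_rate must be in [0, 1]")
  }
  if (p$attendance_prob < 0 || p$attendance_prob > 1) {
    stopf("site_profile(): attendance_prob must be in [0, 1]")
  }
  for (step in c("step2", "step3")) {
    v <- p$therapy_mix[[step]]
    if (abs(sum(v) - 1) > 1e-9) {
      stopf("site_profile(): therapy_mix$%s must sum to 1", step)
    }
  }
  invisible(p)
}

#' Load a packaged fixture site profile
#'
#' Two fixture profiles ship with the package: `"site_a"`, a larger site
#' with longer waits and higher waiting-list attrition, and `"site_b"`, a
#' smaller site with shorter waits and a higher timestamp-corruption rate.
#'
#' @param name `"site_a"` or `"site_b"`.
#' @param n_cases Optional override of the profile's case count.
#' @param seed Optional override of the profile's seed.
#' @return A `site_profile`.
#' @export
packaged_profile <- function(name = c("site_a", "site_b"), n_cases = NULL,
                             seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "profiles", paste0(name, ".yaml"),
                      package = "careflow")
  profile <- read_site_profile(path)
  if (!is.null(n_cases)) profile$n_cases <- n_cases
  if (!is.null(seed)) profile$seed <- as.integer(seed)
  validate_profile(profile)
}

#' Read a site profile from a YAML file
#' @param path Path to a YAML profile (see the packaged `site_a.yaml` for
#'   the schema).
#' @return A `site_profile`.
#' @export
read_site_profile <- function(path) {
  y <- yaml::read_yaml(path)
  site_profile(
    site_name = y$site_name, n_cases = y$n_cases,
    routing = lapply(y$routing, unlist),
    wait_dists = y$wait_dists,
    session_model = y$session_model,
    attendance_prob = y$attendance_prob,
    outcome_model = list(
      pre_mean = y$outcome_model$pre_mean,
      pre_sd = y$outcome_model$pre_sd,
      caseness_threshold = y$outcome_model$caseness_threshold,
      p_recover = unlist(y$outcome_model$p_recover)
    ),
    corruption_rate = y$corruption_rate,
    corruption_magnitude = y$corruption_magnitude,
    therapy_mix = lapply(y$therapy_mix, unlist),
    switch_prob = unlist(y$switch_prob),
    legacy_label_prob = y$legacy_label_prob %||% 0.15,
    window_start = y$window_start %||% "2019-06-01",
    window_weeks = y$window_weeks %||% 104,
    seed = y$seed %||% 1L
  )
}

# -- generation -------------------------------------------------------------

LEGACY_LABELS <- c(referral_received = "referral received (v1)",
                   assessment = "initial_assessment",
                   cbt = "cbt_old")

#' Generate a synthetic stepped-care event log
#'
#' Simulates `profile$n_cases` referrals through the stepped-care pathway
#' under `profile`'s routing probabilities and waiting-time distributions,
#' then applies timestamp corruption at `profile$corruption_rate`. Every
#' case's true event sequence starts at `referral_received` and ends at
#' `discharged`; pre-corruption timestamps are strictly increasing within
#' each case.
#'
#' Ground truth for test oracles is recorded in the case table
#' (`true_route`, the canonical stage sequence implied by the routing
#' draws; `true_route_class`; `true_completed`; `true_recovered`) and in
#' `attr(log, "truth")` (`events`: the uncorrupted event table;
#' `corrupted`: logical per event).
#'
#' @param profile A [site_profile()].
#' @return A `careflow_log`.
#' @export
generate_log <- function(profile) {
  validate_profile(profile)
  set.seed(profile$seed)
  p <- profile
  n <- p$n_cases
  ids <- sprintf("%s_%06d", p$site_name, seq_len(n))
  wk <- WEEK_SECONDS
  wait <- function(nm, k) draw_dist(p$wait_dists[[nm]], k) * wk

  blocks <- list(); bi <- 0L
  add <- function(idx, act, time) {
    bi <<- bi + 1L
    blocks[[bi]] <<- tibble::tibble(i = idx, activity = act, t = time)
  }
  emit_label <- function(canonical, k) {
    out <- rep(canonical, k)
    if (canonical %in% names(LEGACY_LABELS) && p$legacy_label_prob > 0) {
      legacy <- runif(k) < p$legacy_label_prob
      out[legacy] <- LEGACY_LABELS[[canonical]]
    }
    out
  }
  appt_blocks <- list(); ai <- 0L
  add_appts <- function(idx, time, attended, is_treatment) {
    ai <<- ai + 1L
    appt_blocks[[ai]] <<- tibble::tibble(i = idx, t = time,
                                         attended = attended,
                                         is_treatment = is_treatment)
  }

  # per-case state
  t0 <- as.numeric(p$window_start) + runif(n, 0, p$window_weeks * wk)
  reached <- list()  # canonical stages reached, for true_route assembly
  mark <- function(stage, idx) {
    flag <- reached[[stage]] %||% rep(FALSE, n)
    flag[idx] <- TRUE
    reached[[stage]] <<- flag
  }

  add(seq_len(n), emit_label("referral_received", n), t0)
  mark("referral_received", seq_len(n))
  end_time <- rep(NA_real_, n)  # time of entering discharge planning

  # treatment episode simulator: emits therapy movement events + sessions,
  # returns episode end times (last session or switch, whichever is later)
  sim_treatment <- function(idx, step, start) {
    k <- length(idx)
    mix <- p$therapy_mix[[step]]
    therapy1 <- sample(names(mix), k, replace = TRUE, prob = mix)
    add(idx, emit_label_vec(therapy1, p), start)
    switch_on <- runif(k) < p$switch_prob[[step]]
    sw_time <- rep(NA_real_, k)
    if (any(switch_on)) {
      k2 <- sum(switch_on)
      therapy2 <- sample(names(mix), k2, replace = TRUE, prob = mix)
      sw_time[switch_on] <- start[switch_on] + wait("therapy_switch_gap", k2)
      add(idx[switch_on], emit_label_vec(therapy2, p), sw_time[switch_on])
    }
    n_sess <- 1L + as.integer(round(draw_dist(p$session_model$n_sessions, k)))
    n_sess <- pmax(1L, n_sess)
    grp <- rep(seq_len(k), n_sess)
    gaps <- draw_dist(p$session_model$gap, sum(n_sess)) * wk
    first_of_grp <- !duplicated(grp)
    gaps[first_of_grp] <- 0
    offs <- stats::ave(gaps, grp, FUN = cumsum)
    sess_time <- start[grp] + offs
    attended <- runif(sum(n_sess)) < p$attendance_prob
    add_appts(idx[grp], sess_time, attended, rep(TRUE, sum(n_sess)))
    last_sess <- start + stats::ave(offs, grp, FUN = max)[first_of_grp]
    pmax(last_sess, sw_time, na.rm = TRUE)
  }

  # --- routing ------------------------------------------------------------
  r1 <- draw_cat(n, p$routing$post_referral)
  imm <- which(r1 == "discharge"); go <- which(r1 == "proceed")
  end_time[imm] <- t0[imm] + wait("post_referral_discharge", length(imm))

  t_awl <- t0[go] + wait("referral_to_assessment_wl", length(go))
  add(go, rep("assessment_wl", length(go)), t_awl)
  mark("assessment_wl", go)

  r2 <- draw_cat(length(go), p$routing$assessment_waitlist)
  awl_out <- go[r2 == "discharge"]; assessed <- go[r2 == "proceed"]
  t_awl_assessed <- t_awl[r2 == "proceed"]
  end_time[awl_out] <- t_awl[r2 == "discharge"] +
    wait("assessment_wl_to_discharge", length(awl_out))

  t_assess <- t_awl_assessed + wait("assessment_wl_to_assessment", length(assessed))
  add(assessed, emit_label("assessment", length(assessed)), t_assess)
  mark("assessment", assessed)
  add_appts(assessed, t_assess, rep(TRUE, length(assessed)),
            rep(FALSE, length(assessed)))

  r3 <- draw_cat(length(assessed), p$routing$post_assessment)
  pa_out <- assessed[r3 == "discharge"]
  end_time[pa_out] <- t_assess[r3 == "discharge"] +
    wait("post_assessment_discharge", length(pa_out))

  run_step <- function(idx, t_in, step) {
    # waiting list join, attrition-or-treat decision, episode
    wl_stage <- paste0(step, "_wl")
    t_wl <- t_in + wait("assessment_to_triage", length(idx))
    add(idx, rep(wl_stage, length(idx)), t_wl)
    mark(wl_stage, idx)
    dec <- draw_cat(length(idx), p$routing[[paste0(step, "_waitlist")]])
    out <- idx[dec == "discharge"]
    end_time[out] <<- t_wl[dec == "discharge"] +
      wait(paste0(step, "_wl_to_discharge"), length(out))
    treat <- idx[dec == "proceed"]
    t_tx <- t_wl[dec == "proceed"] +
      wait(paste0(step, "_wl_to_treatment"), length(treat))
    mark(paste0(step, "_treatment"), treat)
    ep_end <- if (length(treat) > 0) sim_treatment(treat, step, t_tx) else numeric(0)
    list(treated = treat, ep_end = ep_end)
  }

  s2_in <- assessed[r3 == "step2"]; s3_in <- assessed[r3 == "step3"]
  s2 <- run_step(s2_in, t_assess[r3 == "step2"], "step2")
  # step-2 completers either discharge or step up to the step-3 waiting list
  if (length(s2$treated) > 0) {
    d2 <- draw_cat(length(s2$treated), p$routing$step2_treatment)
    done2 <- s2$treated[d2 == "discharge"]
    end_time[done2] <- s2$ep_end[d2 == "discharge"] +
      wait("treatment_to_discharge", length(done2))
    up <- s2$treated[d2 == "step_up"]
    if (length(up) > 0) {
      sup <- run_step(up, s2$ep_end[d2 == "step_up"] + wait("step_up_gap", length(up)),
                      "step3")
      end_time[sup$treated] <- sup$ep_end +
        wait("treatment_to_discharge", length(sup$treated))
    }
  }
  s3 <- run_step(s3_in, t_assess[r3 == "step3"], "step3")
  if (length(s3$treated) > 0) {
    end_time[s3$treated] <- s3$ep_end +
      wait("treatment_to_discharge", length(s3$treated))
  }

  # discharge pair for everyone
  t_dp <- end_time
  add(seq_len(n), rep("discharge_planning", n), t_dp)
  t_d <- t_dp + wait("discharge_planning_to_discharged", n)
  add(seq_len(n), rep("discharged", n), t_d)
  mark("discharged", seq_len(n))

  # --- assemble event table -----------------------------------------------
  ev <- dplyr::bind_rows(blocks)
  ev <- ev[order(ev$i, ev$t), ]
  events <- tibble::tibble(
    case_id = ids[ev$i],
    activity = ev$activity,
    timestamp = as.POSIXct(round(ev$t), origin = "1970-01-01", tz = "UTC")
  ) |>
    group_by(case_id) |>
    mutate(source_order = row_number()) |>
    ungroup()
  events$imputed <- FALSE
  events$original_timestamp <- as.POSIXct(NA, tz = "UTC")

  appts <- if (ai > 0) dplyr::bind_rows(appt_blocks) else
    tibble::tibble(i = integer(), t = numeric(), attended = logical(),
                   is_treatment = logical())
  appts <- appts[order(appts$i, appts$t), ]
  appointments <- tibble::tibble(
    case_id = ids[appts$i],
    datetime = as.POSIXct(round(appts$t), origin = "1970-01-01", tz = "UTC"),
    attended = appts$attended,
    is_treatment = appts$is_treatment
  )

  # --- ground-truth routes -------------------------------------------------
  stage_seq <- c("referral_received", "assessment_wl", "assessment",
                 "step2_wl", "step2_treatment", "step3_wl", "step3_treatment",
                 "discharged")
  # a case that takes step3 before step2 never happens by construction, so
  # concatenating reached stages in pathway order reproduces the sequence
  flags <- vapply(stage_seq, function(s) reached[[s]] %||% rep(FALSE, n),
                  logical(n))
  true_route <- apply(flags, 1, function(f) route_string(stage_seq[f]))
  true_class <- classify_route_strings(true_route, default_stage_roles())

  # --- outcomes ------------------------------------------------------------
  om <- p$outcome_model
  tx_att <- appointments |>
    filter(is_treatment, attended) |>
    group_by(case_id) |>
    summarise(k = dplyr::n(), .groups = "drop")
  n_att <- setNames(rep(0L, n), ids)
  n_att[tx_att$case_id] <- tx_att$k
  true_completed <- n_att >= 2

  # scores are recorded to 1 dp; caseness is judged on the recorded value
  pre <- round(rnorm(n, om$pre_mean, om$pre_sd), 1)
  first_above <- pre >= om$caseness_threshold
  p_rec <- om$p_recover[true_class]
  p_rec[is.na(p_rec)] <- om$p_recover[["other"]]
  true_recovered <- true_completed & first_above &
    (runif(n) < unname(p_rec))

  scored <- which(n_att >= 1)
  outcomes <- NULL
  if (length(scored) > 0) {
    ks <- unname(n_att[scored])
    thr <- om$caseness_threshold
    last <- ifelse(true_recovered[scored],
                   thr - runif(length(scored), 0.5, 6),
                   thr + runif(length(scored), 0, 8))
    below_start <- !first_above[scored] & !true_recovered[scored]
    last[below_start] <- pre[scored][below_start] + rnorm(sum(below_start), 0, 2)
    grp <- rep(seq_along(scored), ks)
    sidx <- sequence(ks)
    kv <- ks[grp]
    frac <- ifelse(kv == 1, 0, (sidx - 1) / pmax(1, kv - 1))
    sc <- pre[scored][grp] + (last[grp] - pre[scored][grp]) * frac
    noise <- rnorm(length(sc), 0, 1.5)
    noise[sidx == 1 | sidx == kv] <- 0
    sc <- round(sc + noise, 1)
    outcomes <- tibble::tibble(case_id = ids[scored][grp],
                               session_index = as.integer(sidx),
                               score = sc, above_caseness = sc >= thr)
  }

  # --- case attributes -----------------------------------------------------
  cases <- tibble::tibble(
    case_id = ids,
    age = pmax(18L, as.integer(round(rnorm(n, 35, 14)))),
    gender = sample(c("female", "male", "nonbinary", "unspecified"), n,
                    replace = TRUE, prob = c(0.6664, 0.3289, 0.0042, 0.0005)),
    presenting_problem = sample(
      c("anxiety_stress", "depression", "other_mh", "other", "unspecified"),
      n, replace = TRUE, prob = c(0.3189, 0.2665, 0.0277, 0.0031, 0.3838)),
    referral_source = sample(c("self", "gp", "other"), n, replace = TRUE,
                             prob = c(0.9449, 0.0315, 0.0236)),
    imd_decile = ifelse(runif(n) < 0.005, NA_integer_,
                        sample(1:10, n, replace = TRUE)),
    prior_referrals = sample(0:3, n, replace = TRUE,
                             prob = c(0.847, 0.1123, 0.03, 0.0107)),
    referral_date = as.POSIXct(round(t0), origin = "1970-01-01", tz = "UTC"),
    discharge_date = as.POSIXct(round(t_d), origin = "1970-01-01", tz = "UTC"),
    true_route = true_route,
    true_route_class = true_class,
    true_completed = unname(true_completed),
    true_recovered = unname(true_recovered)
  )

  log <- event_log(events, cases, appointments, outcomes)
  corrupt_timestamps(log, rate = p$corruption_rate,
                     magnitude_dist = p$corruption_magnitude,
                     seed = p$seed + 1L)
}

emit_label_vec <- function(labels, p) {
  legacy <- labels %in% names(LEGACY_LABELS) & runif(length(labels)) < p$legacy_label_prob
  labels[legacy] <- LEGACY_LABELS[labels[legacy]]
  labels
}

#' Back-date a fraction of event timestamps
#'
#' Emulates manually entered timestamps that do not reflect the actual
#' event sequence: each non-first event (by `source_order`) is
#' independently selected with probability `rate` and its timestamp is
#' reduced by a draw from `magnitude_dist` (weeks), producing an
#' out-of-order record whenever the draw exceeds the gap to the preceding
#' event. The uncorrupted event table is kept in `attr(out, "truth")`
#' (`events`, plus `corrupted`, a logical vector aligned with the event
#' rows).
#'
#' @param log A `careflow_log` with non-decreasing per-case timestamps.
#' @param rate Selection probability in `[0, 1]`.
#' @param magnitude_dist A [dist_spec()] of back-dating offsets in weeks.
#' @param seed Integer seed controlling selection and offsets.
#' @return The corrupted `careflow_log`.
#' @export
corrupt_timestamps <- function(log, rate, magnitude_dist, seed = 1L) {
  stopifnot(inherits(log, "careflow_log"))
  if (rate < 0 || rate > 1) stopf("corrupt_timestamps(): rate must be in [0, 1]")
  magnitude_dist <- parse_dist(magnitude_dist, "magnitude_dist")
  truth <- list(events = log$events)
  if (rate == 0) {
    truth$corrupted <- rep(FALSE, nrow(log$events))
    attr(log, "truth") <- truth
    return(log)
  }
  set.seed(seed)
  ev <- log$events
  eligible <- ev$source_order > 1L
  selected <- eligible & runif(nrow(ev)) < rate
  offsets <- round(draw_dist(magnitude_dist, sum(selected)) * WEEK_SECONDS)
  ev$timestamp[selected] <- ev$timestamp[selected] - offsets
  out <- log
  out$events <- ev
  truth$corrupted <- selected
  attr(out, "truth") <- truth
  out
}

#' Ground truth attached to a synthetic log
#' @param log A `careflow_log` produced by [generate_log()] or
#'   [corrupt_timestamps()].
#' @return A list with `events` (uncorrupted event table) and `corrupted`
#'   (logical per event row), or `NULL`.
#' @export
log_truth <- function(log) attr(log, "truth")
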