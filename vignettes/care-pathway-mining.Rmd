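---
title: "Mining stepped-care pathways from event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining stepped-care pathways from event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflow)
```

## The problem

Psychological-therapy services organised around *stepped care* offer
low-intensity (step 2) interventions first and "step up" to
high-intensity (step 3) treatment when clinically indicated. Their
electronic records register every movement of a referral through the
pathway — referral received, joining a waiting list, assessment, entry
into a treatment stage, discharge — as a time-stamped event. Treated as
an event log, these records support process mining: discovering the
pathway structure actually in use, quantifying flows and waiting times,
and locating bottlenecks and waiting-list attrition, rather than relying
on isolated aggregate metrics.

`careflow` implements that analysis end to end: event-log ingestion and
validation, repair of out-of-order timestamps, declarative abstraction of
noisy stage vocabularies, directly-follows process maps with performance
annotation and a bottleneck indicator, common-route (variant) analysis
with per-route waiting and recovery summaries, and cohort service
metrics. Because service EHR extracts cannot be shared, the package also
ships a seeded synthetic generator of stepped-care event logs with known
ground truth; every stage of the pipeline is tested against it.

## The event-log model

An event is one movement of one referral (a *case*) into a pathway
stage. A `careflow_log` bundles four tables: `events` (case, stage,
timestamp, recorded order), `cases` (age, gender, presenting problem,
referral source, deprivation decile, prior referrals, ...),
`appointments` (datetime, attended flag, treatment flag) and `outcomes`
(per-session scores with a caseness flag). The recorded entry order
(`source_order`) is treated as the authoritative event sequence;
timestamps are repaired *to* it, never the other way around, because
order-of-entry is system-generated while timestamps are typed by hand.

## Timestamp repair

Manually entered timestamps do not always respect the event sequence. An
event *violates* ordering when its timestamp precedes the running
maximum of earlier timestamps in its case. Repair is last observation
carried forward (LOCF): each violating timestamp is replaced by that
running maximum, which restores non-decreasing order in a single pass
(the operation is idempotent). Repaired events keep their original value
(`original_timestamp`) and an `imputed` flag, and the accompanying
report summarises adjustment sizes — |new − old| in weeks — per event
and per case, over all units and over adjusted units only. Equal
consecutive timestamps are allowed (same-day movements are real).
Forward-looking interpolation variants are deliberately not offered: a
single, order-restoring rule keeps the repair auditable, and the
strategy argument leaves room for extensions.

A useful order-statistic consequence: whenever fewer than half of all
events are adjusted, the median adjustment over *all* events is exactly
0, so a "median 0, IQR 0–0" row in the report is expected, not a bug.

## Abstraction

Raw pathway configurations accumulate near-duplicate stage labels,
administrative stages, and per-therapy detail that overwhelms a process
map. An `abstraction_spec` declares three transformations, applied in a
fixed order, then a coverage filter:

1. **Rename**: map legacy label variants onto canonical labels.
2. **Collapse**: each maximal run of *consecutive* events within one
   subprocess group becomes a single event labelled with the subprocess
   name. The collapsed event carries the run's **first** timestamp, so
   treatment start defines stage entry and the duration to the next
   stage spans the whole subprocess. (Keeping the last timestamp instead
   would fold treatment duration into the preceding wait; first-entry is
   the convention used throughout.)
3. **Exclude**: drop administrative stages. Exclusion runs *after*
   collapsing so that an administrative event cannot split a subprocess
   run in two and inflate the variant count.
4. **Coverage filter**: rank distinct routes by descending case count
   (ties broken lexicographically for determinism) and keep the minimal
   rank prefix whose cumulative case share reaches the requested
   coverage.

Two packaged levels fit the synthetic vocabulary: level A (rename,
collapse the discharge pair, drop waiting lists — for process maps) and
level B (additionally collapse therapies into `step2_treatment` /
`step3_treatment`, keep waiting lists — for route analysis, which needs
the waiting stages).

## The process map

`mine_dfg()` builds a directly-follows graph: edge (a, b) counts
consecutive event pairs "a then b" within cases. Edges carry traversal
counts, distinct-case counts, branching probabilities (traversals out of
a node sum to 1), and median/IQR transition durations in weeks; nodes
carry case counts and stage durations (time to the case's next event;
terminal events contribute none). A case traversing an edge twice
contributes two traversals but one distinct case.

The **bottleneck indicator** of an edge is

> (number of distinct patients moving between the two stages) × (median
> transition duration in weeks),

and edges at or above a chosen quantile of the score distribution
(default 0.99) are flagged. The product is deliberately scale-equivariant:
rescaling all durations by a constant cannot change the flag set.
Distinct cases rather than traversals are used in the score because the
indicator measures patient exposure to the wait, while branching
probabilities use traversals because they describe flow; both counts are
exposed on every edge.

`annotate_semantics()` marks two clinically meaningful edge types from a
stage-role map: waiting-list → discharge edges (*waiting-list
attrition*: discharged before the intended assessment or treatment) and
step-2 → step-3 edges (*step-up*). `export_dot()` renders the map as a
deterministic Graphviz digraph.

## Route analysis

A *route* is a case's full stage sequence. Routes are ranked by case
count and classified into a partition: `stepped_care` (step-2 treatment
later followed by step-3 treatment), attrition classes (a waiting list
joined whose treatment never followed — checked from step 3 down so that
a stepped-up case discharged from the step-3 list is attrition, not
`step2_only`), `step2_only`, `step3_only`, `no_treatment`, `other`.

Per route, the **total wait** is the median over the route's cases of
each case's summed waiting-list stage durations — a median of sums, not
a sum of per-stage medians, because the quantity of interest is a
patient-level total; the per-stage medians are computed too and drive
the timeline chart, where each stage's width is its median duration and
offsets are cumulative.

Outcome proportions partition each route's cases into four bins:
`recovered` (completed treatment, at caseness at the first session,
below at the last), `not_recovered`, `not_at_caseness` (completed but
below the threshold at the start — these are not counted as failures),
and `unknown` (did not complete, or no outcome data). *Completion* means
at least two attended treatment sessions and is reported alongside the
bins rather than inside them, since it cuts across them.

`stepped_care_rate()` decomposes stepped-care cases into those on common
(top-N, default 10) routes and those stepped up through less common
routes; `wait_comparison()` pairs each step's most common treated route
with its attrition counterpart and reports the difference in medians,
plus the step-3 : step-2 treated-wait ratio.

## The synthetic generator

`generate_log()` simulates a service as a branching process: each case
draws an outcome at every decision point (post-referral, assessment
waiting list, post-assessment triage, each treatment waiting list,
step-up after step-2 treatment), waits drawn per transition, a session
model (session count and inter-session gap), Bernoulli attendance, and
pre/post outcome scores with recovery realised at a route-class-specific
probability. Referral arrivals are uniform over a configurable 2-year
window. Waiting times are log-normal by default: service waits are
right-skewed with medians well below means, which a log-normal captures
with two parameters; the family is configurable per transition, and the
shapes are an assumption, not an estimate from any real service.
Attrition branches are given *longer* wait medians than their treated
counterparts by construction, so the qualitative "discharged patients
waited longer" signal is a modelling choice here, reproducible by design
rather than a finding.

Two fixture profiles set the study conditions. `site_a` (the default,
5000 cases) routes 34% of referrals to immediate discharge, 28% of the
assessment waiting list to attrition, 21% of assessed cases to
post-assessment discharge, splits triage 58:42 between steps 2 and 3
with waiting-list attrition of 24% and 32%, steps up 30% of step-2
completers, and corrupts 1.9% of timestamps with log-normal back-dating
offsets (median 2.3 weeks). `site_b` is smaller and faster-moving with a
7.2% corruption rate and small offsets (median 0.5 weeks). Raw logs use
a deliberately messy vocabulary — legacy label variants, per-therapy
stage names (`gsh`, `ccbt`, `cbt`, `counselling`, `emdr`), and a
discharge-planning/discharged pair — so that every abstraction step has
real work to do.

Ground truth is recorded per case (`true_route`, `true_route_class`,
`true_completed`, `true_recovered`) and per event (the uncorrupted
timestamps in `attr(log, "truth")`). The truth route is assembled from
the routing draws themselves, independently of the event table, so it
can serve as an oracle for the abstraction and route modules.

What the generator does **not** emulate: seasonal or pandemic-era demand
shifts, re-referrals and patient-level (rather than referral-level)
journeys, therapist capacity coupling between cases (waits are drawn
independently), missingness mechanisms beyond a small random IMD-decile
gap, and any site's actual parameter values — the profiles are shaped
contrasts, not fits. Passing tests therefore demonstrate correctness of
the pipeline's computations and recoverability of known parameters, not
clinical realism of the inputs.

## Numerical conventions

* Durations are weeks (= days / 7) throughout; printed to 1 decimal.
* Percentages are rounded half-even (R's `round()`) to 2 decimals
  (1 for the imputation rate), matching service-report precision.
* Medians and IQRs use linear-interpolation (type-7) quantiles so
  results are reproducible bit-for-bit across implementations.
* Coverage ties: equal-count variants rank lexicographically.
* Zero-duration transitions are permitted (same-day movements).
* Synthetic timestamps are whole seconds, making the ISO-8601 CSV round
  trip lossless.
* Degenerate inputs: an empty log mines to an empty map; a log whose
  cases are all filtered away errors early with a stage-named message;
  a recovery denominator of zero is reported as `NA`, not 0.

## Problem sizes and test design

The statistical tests run against a standard 5000-case `site_a` log —
large enough that three binomial standard errors separate all the
designed branching probabilities from their neighbours — and the repair
test uses a ~120,000-event log corrupted at 7.2%. Miner correctness is
established against a brute-force pair-counting oracle on 200 random
small logs (≤10 cases, ≤8 stages) rather than against a reference
library, keeping the check independent of any one implementation. The
full suite runs in well under a minute.

## Limitations

* LOCF is the only repair strategy; systematically *early* first events
  in a case cannot be detected by any order-based rule.
* The coverage filter operates on full-route identity; near-identical
  routes are not merged.
* Route classification assumes the stage-role map covers the vocabulary;
  unknown stages fall into `other` rather than erroring.
* The analysis is referral-level: a patient re-referred after discharge
  appears as an unrelated case.
* No statistical test of the wait–attrition association is provided;
  the wait comparison is descriptive.
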