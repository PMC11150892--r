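# Fixture profile: the larger of the two synthetic sites, with longer
# waiting times and higher waiting-list attrition. Routing probabilities
# and wait medians (weeks) follow the branching proportions and median
# waits typical of a large stepped-care talking-therapies service.
site_name: site_a
n_cases: 5000
seed: 20190601
routing:
  post_referral:        {proceed: 0.66, discharge: 0.34}
  assessment_waitlist:  {proceed: 0.7185, discharge: 0.2815}
  post_assessment:      {step2: 0.4558, step3: 0.3361, discharge: 0.2081}
  step2_waitlist:       {proceed: 0.7597, discharge: 0.2403}
  step2_treatment:      {discharge: 0.70, step_up: 0.30}
  step3_waitlist:       {proceed: 0.6798, discharge: 0.3202}
  step3_treatment:      {discharge: 1.0}
wait_dists:
  post_referral_discharge:          {family: lognormal, median: 1.0, sdlog: 0.6}
  referral_to_assessment_wl:        {family: lognormal, median: 0.05, sdlog: 0.3}
  assessment_wl_to_assessment:      {family: lognormal, median: 4.0, sdlog: 0.6}
  assessment_wl_to_discharge:       {family: lognormal, median: 8.0, sdlog: 0.6}
  assessment_to_triage:             {family: lognormal, median: 0.1, sdlog: 0.3}
  post_assessment_discharge:        {family: lognormal, median: 2.0, sdlog: 0.6}
  step2_wl_to_treatment:            {family: lognormal, median: 9.3, sdlog: 0.6}
  step2_wl_to_discharge:            {family: lognormal, median: 16.6, sdlog: 0.6}
  step3_wl_to_treatment:            {family: lognormal, median: 30.0, sdlog: 0.6}
  step3_wl_to_discharge:            {family: lognormal, median: 37.9, sdlog: 0.6}
  step_up_gap:                      {family: lognormal, median: 0.3, sdlog: 0.3}
  treatment_to_discharge:           {family: lognormal, median: 1.0, sdlog: 0.4}
  discharge_planning_to_discharged: {family: lognormal, median: 0.05, sdlog: 0.3}
  therapy_switch_gap:               {family: lognormal, median: 2.0, sdlog: 0.3}
session_model:
  n_sessions: {family: fixed, location: 6}   # 1 + round(draw): 7 sessions
  gap:        {family: lognormal, median: 1.0, sdlog: 0.3}
attendance_prob: 0.895
outcome_model:
  pre_mean: 14
  pre_sd: 4
  caseness_threshold: 10
  p_recover: {step2_only: 0.50, step3_only: 0.46, stepped_care: 0.42, other: 0.40}
corruption_rate: 0.019
corruption_magnitude: {family: lognormal, median: 2.3, sdlog: 1.0}
therapy_mix:
  step2: {gsh: 0.7, ccbt: 0.3}
  step3: {cbt: 0.6, counselling: 0.3, emdr: 0.1}
switch_prob: {step2: 0.25, step3: 0.15}
legacy_label_prob: 0.15
window_start: "2019-06-01"
window_weeks: 104
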