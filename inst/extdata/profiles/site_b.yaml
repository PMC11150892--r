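# Fixture profile: the smaller synthetic site — shorter waits, less
# waiting-list attrition, more missed appointments, and a markedly higher
# timestamp-corruption rate with smaller back-dating offsets.
site_name: site_b
n_cases: 1500
seed: 20190602
routing:
  post_referral:        {proceed: 0.78, discharge: 0.22}
  assessment_waitlist:  {proceed: 0.853, discharge: 0.147}
  post_assessment:      {step2: 0.43, step3: 0.33, discharge: 0.24}
  step2_waitlist:       {proceed: 0.83, discharge: 0.17}
  step2_treatment:      {discharge: 0.68, step_up: 0.32}
  step3_waitlist:       {proceed: 0.77, discharge: 0.23}
  step3_treatment:      {discharge: 1.0}
wait_dists:
  post_referral_discharge:          {family: lognormal, median: 0.8, sdlog: 0.6}
  referral_to_assessment_wl:        {family: lognormal, median: 0.05, sdlog: 0.3}
  assessment_wl_to_assessment:      {family: lognormal, median: 3.0, sdlog: 0.6}
  assessment_wl_to_discharge:       {family: lognormal, median: 6.0, sdlog: 0.6}
  assessment_to_triage:             {family: lognormal, median: 0.1, sdlog: 0.3}
  post_assessment_discharge:        {family: lognormal, median: 1.5, sdlog: 0.6}
  step2_wl_to_treatment:            {family: lognormal, median: 5.1, sdlog: 0.6}
  step2_wl_to_discharge:            {family: lognormal, median: 10.1, sdlog: 0.6}
  step3_wl_to_treatment:            {family: lognormal, median: 18.0, sdlog: 0.6}
  step3_wl_to_discharge:            {family: lognormal, median: 23.8, sdlog: 0.6}
  step_up_gap:                      {family: lognormal, median: 0.3, sdlog: 0.3}
  treatment_to_discharge:           {family: lognormal, median: 1.0, sdlog: 0.4}
  discharge_planning_to_discharged: {family: lognormal, median: 0.05, sdlog: 0.3}
  therapy_switch_gap:               {family: lognormal, median: 2.0, sdlog: 0.3}
session_model:
  n_sessions: {family: fixed, location: 5}   # 1 + round(draw): 6 sessions
  gap:        {family: lognormal, median: 1.0, sdlog: 0.3}
attendance_prob: 0.88
outcome_model:
  pre_mean: 14
  pre_sd: 4
  caseness_threshold: 10
  p_recover: {step2_only: 0.55, step3_only: 0.51, stepped_care: 0.47, other: 0.45}
corruption_rate: 0.072
corruption_magnitude: {family: lognormal, median: 0.5, sdlog: 0.8}
therapy_mix:
  step2: {gsh: 0.6, ccbt: 0.4}
  step3: {cbt: 0.55, counselling: 0.3, emdr: 0.15}
switch_prob: {step2: 0.2, step3: 0.2}
legacy_label_prob: 0.1
window_start: "2019-06-01"
window_weeks: 104
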