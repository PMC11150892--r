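# Abstraction level A for the synthetic stage vocabulary: rename legacy
# label variants, collapse the discharge-planning/discharged pair, and
# exclude waiting-list (administrative) stages. Individual therapy stages
# are kept so the process map shows per-treatment waits.
name: A
rename_map:
  "referral received (v1)": referral_received
  "initial_assessment": assessment
  "cbt_old": cbt
subprocess_groups:
  discharged: [discharge_planning, discharged]
exclusions: [assessment_wl, step2_wl, step3_wl]
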