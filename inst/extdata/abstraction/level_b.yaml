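# Abstraction level B: as level A but therapies are collapsed into
# step-level treatment subprocesses and waiting-list stages are retained,
# which route analysis relies on.
name: B
rename_map:
  "referral received (v1)": referral_received
  "initial_assessment": assessment
  "cbt_old": cbt
subprocess_groups:
  discharged: [discharge_planning, discharged]
  step2_treatment: [gsh, ccbt]
  step3_treatment: [cbt, counselling, emdr]
exclusions: []
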