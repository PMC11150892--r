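site,measure,numerator,denominator,printed_pct,dp
site_1,treatment_completion,18058,45401,39.77,2
site_2,treatment_completion,5220,12590,41.46,2
site_1,recovery,8212,17151,47.88,2
site_2,recovery,2632,5034,52.28,2
site_1,recovery_data_completeness,17151,18058,94.98,2
site_2,recovery_data_completeness,5034,5220,96.44,2
site_1,missed_appointments,21757,206564,10.53,2
site_2,missed_appointments,6524,55415,11.77,2
site_1,coverage,43183,45401,95.11,2
site_1,imputation,6491,336637,1.9,1
site_2,imputation,8921,123523,7.2,1
site_1,immediate_discharge_of_all,14659,43183,33.95,2
site_1,post_assessment_discharge_of_assessed,5935,28524,20.81,2
site_1,post_assessment_discharge_of_all,5935,43183,13.74,2
site_1,pre_treatment_attrition_of_triaged,6193,22589,27.42,2
site_1,pre_treatment_attrition_of_all,6193,43183,14.34,2
site_1,pre_treatment_attrition_step2_of_step2,3124,13003,24.03,2
site_1,pre_treatment_attrition_step3_of_step3,3069,9586,32.02,2
site_1,assessment_wl_discharge_of_all,8437,45401,18.58,2
site_2,assessment_wl_discharge_of_all,1442,12590,11.45,2
site_1,post_assessment_discharge_of_all_referrals,5970,45401,13.15,2
site_2,post_assessment_discharge_of_all_referrals,3035,12590,24.11,2
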