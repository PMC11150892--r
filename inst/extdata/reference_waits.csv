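site,step,treated_median_weeks,attrition_median_weeks,printed_difference_weeks
site_1,step2,13.3,20.6,7.3
site_1,step3,34,41.9,7.9
site_2,step2,8.1,13.1,5
site_2,step3,21,26.8,5.8
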