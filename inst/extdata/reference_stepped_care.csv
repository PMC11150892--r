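site,common,uncommon,total_cases,printed_total,printed_pct
site_1,1117,390,45401,1507,3.32
site_2,365,162,12590,527,4.19
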