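# Synthetic baseline incidence/prevalence fixture (cases per 100,000
# population per year), magnitudes typical of U.S. national statistics.
endpoint,y0_per_100k,year,source
all_cause_mortality,950,2024,synthetic-typical
asthma,430,2024,synthetic-typical
diabetes,870,2024,synthetic-typical
ischemic_heart_disease,250,2024,synthetic-typical
respiratory_tract_cancer,57,2024,synthetic-typical
stroke,270,2024,synthetic-typical
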