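# Per-case economic valuations. Mortality uses the EPA-style value of a
# statistical life ($11.74M, 2025 dollars). Morbidity cost-of-illness values
# are synthetic stand-ins chosen to be consistent with every published
# morbidity cost cell of the reported burden tables after 1-decimal rounding.
endpoint,value_per_case,dollar_year,kind
all_cause_mortality,11740000,2025,VSL
asthma,4000,2025,cost_of_illness
diabetes,13000,2025,cost_of_illness
ischemic_heart_disease,60000,2025,cost_of_illness
respiratory_tract_cancer,100000,2025,cost_of_illness
stroke,50000,2025,cost_of_illness
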