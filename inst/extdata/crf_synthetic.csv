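# Synthetic concentration-response fixture: field-typical relative risks per
# stated long-term concentration increment, standing in for endpoint-specific
# RRs from regulatory assessments and meta-analyses. The pollutant-endpoint
# pair set matches the default analysis (PM: six endpoints; NOx: mortality,
# asthma, IHD; SO2: mortality, IHD; CO: mortality, IHD).
pollutant,endpoint,rr,increment_ugm3,source
PM,all_cause_mortality,1.06,10,synthetic-typical
PM,asthma,1.05,10,synthetic-typical
PM,diabetes,1.10,10,synthetic-typical
PM,ischemic_heart_disease,1.02,10,synthetic-typical
PM,respiratory_tract_cancer,1.08,10,synthetic-typical
PM,stroke,1.02,10,synthetic-typical
NOx,all_cause_mortality,1.02,10,synthetic-typical
NOx,asthma,1.26,10,synthetic-typical
NOx,ischemic_heart_disease,1.01,10,synthetic-typical
SO2,all_cause_mortality,1.01,10,synthetic-typical
SO2,ischemic_heart_disease,1.01,10,synthetic-typical
CO,all_cause_mortality,1.002,1000,synthetic-typical
CO,ischemic_heart_disease,1.002,1000,synthetic-typical
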