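# Synthetic per-throughput emission factors (kg pollutant per ton of waste
# burned, uncontrolled basis) of AP-42-like magnitude for a medical waste
# incinerator.
pollutant,factor_kg_per_ton,basis,source
PM,2.33,uncontrolled,synthetic-ap42-style
NOx,1.78,uncontrolled,synthetic-ap42-style
SO2,1.09,uncontrolled,synthetic-ap42-style
CO,0.30,uncontrolled,synthetic-ap42-style
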