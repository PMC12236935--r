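# Control-technology removal efficiencies (fraction removed). NOx reflects
# the standard 50% retrofit reduction assumption; PM and SO2 efficiencies are
# consistent with the controlled/uncontrolled case ratios of the reported
# burden tables (fabric filtration and dry sorbent injection respectively);
# CO is uncontrolled by these technologies.
pollutant,efficiency,technology
PM,0.984,ACI/FF
NOx,0.50,retrofit-guidance
SO2,0.67,DSI
CO,0.0,none
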