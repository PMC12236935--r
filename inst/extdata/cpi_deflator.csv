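# BLS CPI-U annual averages (U.S. city average, all items, 1982-84=100).
# 2010-2024 from the published series; 2025 is a projection used as the
# reporting year index.
year,index
2010,218.056
2014,236.736
2015,237.017
2016,240.007
2017,245.120
2018,251.107
2019,255.657
2020,258.811
2021,270.970
2022,292.655
2023,304.702
2024,313.689
2025,322.000
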