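# Published annual totals (kg of active ingredient) of veterinary
# antimicrobial imports into Fiji, 2017-2021 (the table's Total row,
# computed by the source from unrounded data).
year,total_kg
2017,129.93
2018,134.08
2019,153.56
2020,19.22
2021,27.51
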