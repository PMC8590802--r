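individual_id,sex,study_area,n_fixes,area_km2
SB01,F,eastern,112,7.70
SB02,F,eastern,88,8.90
SB03,F,eastern,235,10.30
SB04,F,eastern,61,11.60
SB05,M,eastern,44,12.40
SB06,F,eastern,319,13.10
SB07,F,eastern,150,13.80
SB08,F,eastern,97,14.60
SB09,F,southern,205,23.35
SB10,M,eastern,31,27.85
SB11,M,eastern,402,31.00
SB12,M,eastern,76,35.00
SB13,F,southern,118,55.00
SB14,F,southern,290,63.80
SB15,F,southern,182,77.82
SB16,M,southern,55,82.00
SB17,M,southern,630,86.98
SB18,M,eastern,140,90.00
SB19,M,eastern,210,97.22
SB20,M,southern,95,165.66
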