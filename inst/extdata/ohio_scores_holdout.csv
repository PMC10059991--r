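algorithm,patient,precision,recall,f1,accuracy
flea,540,0.64,0.63,0.63,0.63
flea,544,0.72,0.70,0.70,0.70
flea,552,0.65,0.60,0.61,0.60
flea,567,0.64,0.63,0.63,0.63
flea,584,0.69,0.67,0.67,0.67
flea,596,0.71,0.66,0.67,0.66
flea,avg,0.68,0.65,0.65,0.65
non_fl,540,0.62,0.61,0.61,0.61
non_fl,544,0.72,0.70,0.70,0.70
non_fl,552,0.62,0.58,0.57,0.58
non_fl,567,0.62,0.62,0.62,0.62
non_fl,584,0.67,0.66,0.65,0.66
non_fl,596,0.69,0.65,0.65,0.65
non_fl,avg,0.66,0.64,0.63,0.64
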