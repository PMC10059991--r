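model,p540,p544,p552,p567,p584,p596
non_fl,0.6075,0.7024,0.5748,0.6193,0.6504,0.6524
flea,0.6261,0.7036,0.6077,0.6312,0.6667,0.6681
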