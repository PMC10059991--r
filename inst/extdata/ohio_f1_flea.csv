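model,p559,p563,p570,p575,p588,p591
559,0.7304,0.7210,0.8047,0.6337,0.7320,0.6015
563,0.7278,0.7141,0.7947,0.6113,0.7193,0.6043
570,0.7194,0.7312,0.8314,0.5986,0.7235,0.5952
575,0.7234,0.7177,0.8016,0.6472,0.7339,0.6052
588,0.7260,0.7287,0.8206,0.6230,0.7216,0.6020
591,0.7260,0.7214,0.8180,0.6199,0.7291,0.5932
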