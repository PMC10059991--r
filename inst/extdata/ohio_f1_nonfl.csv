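model,p559,p563,p570,p575,p588,p591
559,0.7006,0.5731,0.6803,0.5878,0.6823,0.5486
563,0.6820,0.7072,0.8294,0.5679,0.6975,0.5635
570,0.7270,0.7233,0.8269,0.6291,0.7312,0.6061
575,0.7052,0.6726,0.7657,0.6423,0.6935,0.5866
588,0.6466,0.5395,0.7167,0.4996,0.7310,0.5134
591,0.6577,0.6913,0.7579,0.5637,0.6761,0.5796
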