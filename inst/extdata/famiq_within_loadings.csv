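parameter,cfa_est,cfa_se,ref_est,ref_se,n
cards,0.979,0.049,1.001,0.069,400
matrices,0.906,0.048,0.962,0.068,400
animals,1.093,0.056,1.026,0.071,400
occupats,1.071,0.056,0.901,0.064,400
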