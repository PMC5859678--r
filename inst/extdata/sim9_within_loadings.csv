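parameter,cfa_est,cfa_se,ref_est,ref_se,n
V2,0.774,0.010,0.799,0.009,10000
V3,0.801,0.010,0.792,0.009,10000
V4,0.673,0.010,0.791,0.009,10000
V5,0.603,0.009,0.802,0.009,10000
V6,0.599,0.010,0.794,0.009,10000
V7,0.576,0.009,0.798,0.009,10000
V8,0.625,0.009,0.787,0.009,10000
V9,0.633,0.009,0.798,0.009,10000
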