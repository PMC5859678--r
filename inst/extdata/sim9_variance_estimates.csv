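model,lambda_v1,factor_var,resid_var_v1
mcfa,0.800,1.001,0.357
cfa,0.800,1.985,0.791
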