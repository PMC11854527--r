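task,beta,fp,fn,tp
whole_tumor,0.25,134,347,3170
whole_tumor,0.5,134,350,3167
whole_tumor,0.75,134,350,3167
whole_tumor,1.5,136,349,3168
whole_tumor,5,136,349,3168
whole_tumor,10,136,349,3168
core_tumor,0.25,9,206,849
core_tumor,0.5,25,107,948
core_tumor,0.75,25,105,950
core_tumor,1.5,25,105,950
core_tumor,5,25,105,950
core_tumor,10,25,105,950
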