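combination,tp,tn,n_pos,n_neg
GLCM48,43,48,59,61
GLCM48_PLUS_GLOBAL3,44,46,59,61
GGCM15,48,50,59,61
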