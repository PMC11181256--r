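reader_id,tp,tn,n_pos,n_neg
Experienced 1,38,46,59,61
Experienced 2,39,46,59,61
Experienced 3,40,43,59,61
Junior 1,40,42,59,61
Junior 2,37,46,59,61
Junior 3,38,44,59,61
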