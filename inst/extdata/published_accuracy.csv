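label,n_published,accuracy_pct_published
L|L,6,100
L|LM,1,100
LM|LM,1,100
M|LM,4,100
H|LM,2,50.0
M|M,33,42.4
H|M,23,87.0
H|H,14,71.4
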