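yield_pct,rel_error_pct
0,100
10,50
30,15
50,10
100,10
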