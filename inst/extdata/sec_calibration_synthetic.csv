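fraction,kDa
18,2000
24,978
28,752
32,461
40,96
42,55
48,14
56,1.3
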