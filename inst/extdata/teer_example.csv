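time_h,resistance_ohm,blank_ohm
0,142,38
0.5,138,38
1,131,37
2,118,37
4,102,38
6,95,38
8,91,38
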