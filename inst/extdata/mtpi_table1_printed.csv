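n,escalate_le,deescalate_ge
3,0,2
6,1,3
9,1,4
12,2,5
15,2,7
18,3,8
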