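marker,group,position_cM
3_0163,5H,0
2_0553,5H,2.15
3_0984,5H,4.30
3_0979,5H,5.38
3_0975,5H,5.38
3_0977,5H,5.38
3_0001,5H,5.38
3_1022,5H,5.38
3_1023,5H,5.38
2_1221,5H,10.78
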