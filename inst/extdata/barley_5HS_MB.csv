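marker,group,position_cM
1_0745,5H,0
2_0894,5H,0
2_0553,5H,1.07
3_0543,5H,1.07
3_0983,5H,2.15
3_0975,5H,2.15
3_1023,5H,2.15
3_0591,5H,3.23
2_0206,5H,3.23
2_1202,5H,4.30
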