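marker,group,position_cM
1_0745,5H,0
2_0894,5H,0
3_0543,5H,0
3_0984,5H,0
2_0226,5H,0
3_0978,5H,0
3_0979,5H,0
3_0980,5H,0
3_0975,5H,0
3_0976,5H,0
3_0001,5H,0
3_1023,5H,0
3_0591,5H,0
2_0206,5H,1.09
1_1381,5H,2.17
2_1202,5H,2.17
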