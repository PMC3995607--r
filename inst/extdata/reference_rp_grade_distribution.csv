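rp_grade,count
0,10
1,31
2,27
3,23
4,1
5,8
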