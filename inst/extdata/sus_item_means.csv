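item,mean
1,4.17
2,2.17
3,4.17
4,1.83
5,3.50
6,2.17
7,4.17
8,2.17
9,3.83
10,1.83
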