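y,x
0,1
0,2
0,3
0,4
1,5
0,6
1,7
1,8
1,9
1,10
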