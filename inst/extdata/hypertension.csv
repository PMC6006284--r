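x,z,cases,controls
1,1,20,18
1,0,13,24
0,1,161,261
0,0,117,319
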