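HU,RED
-1000,0
0,1
1500,1.85
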