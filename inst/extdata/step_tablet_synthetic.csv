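"nominal_od","measured_pixel"
0.05,227
0.2,161
0.35,114
0.5,81
0.65,57
0.8,40
0.95,29
1.1,20
1.25,14
1.4,10
1.55,7
1.7,5
1.85,4
2,3
2.15,2
2.3,1
2.75,0
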