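analyte,H0,width,a_CE,a_CE2,a_CID,a_CID2
PGE2-d4,110000,6.5,-0.95,-1.9,0,0
LXA4-d5,75000,7.0,0,-1.6,0.1,-0.05
LTB4-d4,140000,6.0,1.1,-2.2,0,0
9-HODE-d4,280000,7.5,1.4,-1.4,0,0
5-HETE-d8,240000,6.8,-2.4,-2.4,-0.08,-0.04
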