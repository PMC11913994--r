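analyte,H0,width,b_CID,b_IntT,b_IntV,b_CID2,b_IntT2,b_IntV2,b_CID_IntT,b_IntT_IntV,b_HG,b_DG,b_HB,b_DL
PGE2-d4,120000,6.5,0.28,0.132,-0.24,-0.22,-0.12,-0.12,0,0,0.0005,-0.0005,0.0005,-0.0005
LXA4-d5,80000,7.0,0.1147,0.0653,-0.22,-0.17,-0.08,-0.11,0,0.06,0.0005,-0.0005,0.0005,-0.0005
LTB4-d4,150000,6.0,0.2504,0.1244,-0.12,-0.17,-0.07,-0.06,0.08,0,-0.0005,0.0005,-0.0005,0.0005
9-HODE-d4,300000,7.5,0.122,0.0587,-0.12,-0.17,-0.07,-0.06,0.08,0,-0.0005,0.0005,-0.0005,0.0005
5-HETE-d8,250000,6.8,0.0509,0.144,-0.1,-0.28,-0.06,-0.05,0,0,0.0005,-0.0005,-0.0005,0.0005
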