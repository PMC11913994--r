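analyte,sn_pre,sn_post,loq_pre_printed,loq_post_printed,gain_height,gain_auc,suppress_k
20-OH-LTB4,5.9,17.2,0.5,0.5,1.78,1.42,0.270
TXB2,5.2,12.5,1,0.5,1.80,1.44,0.010
PGF2a,8.1,11.7,2,1,1.70,1.36,0.010
PGE2,8.9,12.4,1,0.5,1.75,1.40,0.010
PGD2,12.8,15.7,1,1,1.66,1.30,0.410
LXA4,5.7,10.1,1,1,1.72,1.38,0.160
RvD5,5.2,11.5,1,0.5,1.85,1.48,0.010
t-LTB4,10.8,30.2,1,0.5,2.05,1.60,0.225
LTB4,7.1,24.7,1,0.5,2.10,1.63,0.145
13-HoTrE,5.8,14.6,4,2,1.90,1.52,0.010
9-HODE,15.6,32.7,1,1,1.95,1.56,0.410
15-HETE,6.9,25.9,2,1,2.05,1.60,0.315
12-HETE,8.9,36.7,2,0.5,2.12,1.64,0.010
5-HETE,8.9,44.2,1,0.24,2.15,1.66,0.055
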