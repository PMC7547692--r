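month,mean_mm,p_wet,shape,scale,p_wet_wet
1,3.2,0.04,0.85,3.03605313092979,0.39
2,5.4,0.07,0.85,3.21261247861977,0.42
3,16.2,0.13,0.85,4.72923660779448,0.48
4,27,0.17,0.85,6.22837370242215,0.52
5,43.2,0.23,0.85,7.12812474218299,0.58
6,59.5,0.27,0.85,8.64197530864197,0.62
7,129.7,0.35,0.85,14.0634318243426,0.7
8,124.3,0.35,0.85,13.477907291949,0.7
9,86.5,0.3,0.85,11.3071895424837,0.65
10,48.6,0.19,0.85,9.70738040547289,0.54
11,13,0.1,0.85,5.09803921568628,0.45
12,3.4,0.04,0.85,3.2258064516129,0.39
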