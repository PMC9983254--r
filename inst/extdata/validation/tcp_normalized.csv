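position,x_mm,y_mm,z_mm
0,1064.00,97.02,-201.19
1,1059.64,96.45,-200.66
2,1058.72,95.69,-199.79
3,1061.02,95.15,-201.05
4,1061.25,95.07,-200.22
5,1059.90,97.93,-199.14
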