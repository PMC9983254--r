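position,x_mm,y_mm,z_mm
0,-0.003,0.378,0.218
1,-0.002,0.667,0.126
2,0.000,0.104,-0.025
3,0.001,-0.159,0.041
4,0.184,-0.241,0.178
5,0.001,-0.089,0.005
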