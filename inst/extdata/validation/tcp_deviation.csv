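position,x_mm,y_mm,z_mm
0,-0.393,-0.016,-0.100
1,-1.618,0.651,0.037
2,0.380,-0.181,0.486
3,0.159,-0.497,-0.465
4,0.360,-0.951,0.148
5,1.110,0.995,-0.108
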