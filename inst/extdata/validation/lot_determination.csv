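position,x_mm,y_mm,z_mm,lot_cad_mm,lot_transform_mm
0,25.737,-0.005,365.337,366.242,367.96
1,26.137,-1.822,365.124,366.063,367.69
2,25.777,-0.326,365.467,366.375,366.54
3,25.353,-1.013,365.626,366.505,367.37
4,25.380,-0.270,365.600,366.480,366.79
5,24.015,0.963,366.347,367.135,367.10
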