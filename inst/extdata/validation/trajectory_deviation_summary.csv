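stat,dX_mm,dY_mm,dZ_mm,euclidean_mm
average,3.44,-0.36,0.17,3.59
max,3.66,0.24,1.50,3.79
min,3.26,-0.59,-1.57,3.41
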