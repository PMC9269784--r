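feature,p_value,significant
max3ddiam,0.029,no
surfarea,0.012,yes
volume,0.011,yes
ael,0.334,no
afl,0.015,yes
aco,0.017,yes
kel,0.382,no
kfl,0.014,yes
mps,0.019,yes
sphericity,0.036,no
vdn,0.047,no
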