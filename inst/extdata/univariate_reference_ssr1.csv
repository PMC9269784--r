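feature,p_value,significant
max3ddiam,0.001,yes
surfarea,<0.001,yes
volume,<0.001,yes
ael,0.193,no
afl,0.009,yes
aco,0.008,yes
kel,0.200,no
kfl,0.010,yes
mps,0.005,yes
sphericity,0.280,no
vdn,0.274,no
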