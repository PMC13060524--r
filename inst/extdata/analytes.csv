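name,molecular_weight_da,alpha_prime_A3,hydrodynamic_radius_nm
glycine,75.07,1.5,0.28
alanine,89.09,3,0.31
threonine,119.12,6,0.34
histidine,155.15,12,0.36
tryptophan,204.23,25,0.38
o-phospho-threonine,199.10,32,0.36
myc-tag,1203,50,0.75
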