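# SYNTHETIC cation-pi Lennard-Jones table for the HPS-cation-pi model.
# Uniform surrogate well depth; eps kJ/mol, sigma nm.
i,j,eps,sigma
R,F,3.35,0.646
K,F,3.35,0.636
R,W,3.35,0.667
K,W,3.35,0.657
R,Y,3.35,0.651
K,Y,3.35,0.641
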