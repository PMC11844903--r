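# SYNTHETIC Yukawa amplitude table for the Mpipi-Recharged model.
# Surrogate values: sign structure follows the charge product; the
# pair-specific modulation is not reducible to single-residue factors.
# A in kJ nm/mol.
i,j,A
R,R,1.9493
R,K,1.8607
K,K,1.7721
R,D,-1.5063
K,D,-1.6835
D,D,1.9493
R,E,-1.5949
K,E,-1.7721
D,E,1.8607
E,E,1.7721
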