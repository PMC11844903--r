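HPS:
  residue_table: hps_kr_residues.csv
  hydrophobic: ashbaugh_hatch
  ah_eps: 0.8368
  electrostatic: debye_huckel_fixed
  kappa: 1.0
  eps_r: 80.0
  bond_k: 9.6
  bond_r0: 3.81
  elec_cutoff: 3.5
  hyd_cutoff_factor: 3.0
HPS-cation-pi:
  residue_table: hps_kr_residues.csv
  hydrophobic: ashbaugh_hatch
  ah_eps: 0.8368
  electrostatic: debye_huckel_fixed
  kappa: 1.0
  eps_r: 80.0
  cation_pi_table: hps_cation_pi_synthetic.csv
  bond_k: 2.4
  bond_r0: 3.81
  elec_cutoff: 3.5
  hyd_cutoff_factor: 3.0
HPS-Urry:
  residue_table: hps_urry_residues.csv
  hydrophobic: ashbaugh_hatch
  ah_eps: 0.8368
  electrostatic: debye_huckel_fixed
  kappa: 1.0
  eps_r: 80.0
  bond_k: 4.8
  bond_r0: 3.81
  elec_cutoff: 2.0
  hyd_cutoff_factor: 3.0
CALVADOS2:
  residue_table: calvados2_residues.csv
  hydrophobic: ashbaugh_hatch
  ah_eps: 0.8368
  electrostatic: debye_huckel_salt_T
  salt: 150.0
  bond_k: 9.6
  bond_r0: 3.81
  elec_cutoff: 4.0
  hyd_cutoff_factor: 3.0
Mpipi:
  residue_table: mpipi_residues.csv
  hydrophobic: wang_frenkel
  pair_table: mpipi_pairs_synthetic.csv
  electrostatic: debye_huckel_fixed
  kappa: 1.26
  eps_r: 80.0
  bond_k: 9.6
  bond_r0: 3.81
  elec_cutoff: 3.5
  hyd_cutoff_factor: 3.0
Mpipi-Recharged:
  residue_table: mpipi_residues.csv
  hydrophobic: wang_frenkel
  pair_table: mpipi_pairs_synthetic.csv
  electrostatic: yukawa
  salt: 150.0
  yukawa_table: mpipi_recharged_yukawa_synthetic.csv
  bond_k: 9.6
  bond_r0: 3.81
  elec_cutoff: 3.5
  hyd_cutoff_factor: 3.0
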