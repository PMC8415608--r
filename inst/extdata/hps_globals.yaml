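schema_version: 1
pair_model: HPS
sigma_convention: pair-potential contact diameter in Angstrom; sigma_ij and lambda_ij are arithmetic means
epsilon: 0.2
dielectric: 80.0
debye_length: 10.0
bond_k: 2.39006
bond_r0: 3.8
lj_cutoff: 20.0
coul_cutoff: 35.0
kh_alpha: 0.228
kh_e0: -1.0
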