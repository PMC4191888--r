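polymer:
  n_monomers: 1050
lattice:
  L: 500
looping:
  mode: uniform_adapted
  p_short: 0.12
  p_long: 0.04
  short_cutoff: 50
  t_bond: 8000.0
  max_bonds_per_monomer: 1
protocol:
  equil1_mcs: 1.0e+08
  equil2_mcs: 1.0e+08
  save_interval: 1.0e+07
  n_conformations: 1000
  seed: 1
output:
  dir: runs/full_scale
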