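polymer:
  n_monomers: 105
lattice:
  L: 64
looping:
  mode: uniform_adapted
  p_short: 0.03
  p_long: 0.03
  t_bond: 8000.0
  max_bonds_per_monomer: 1
protocol:
  equil1_mcs: 10000.0
  equil2_mcs: 10000.0
  save_interval: 1000.0
  n_conformations: 20
  seed: 1
output:
  dir: runs/test
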