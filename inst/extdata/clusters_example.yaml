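# Example standard-model cluster specification for makeStdModel / detectMC.
# Coordinates are 1-based (row, col), row 1 at the top.
seed: 42
clusters:
  - center: [220, 180]
    n_mcs: 4
    mc_radius_range: [1, 2]
    cluster_radius: 12
  - center: [340, 120]
    n_mcs: 5
    mc_radius_range: [1, 2.5]
    cluster_radius: 15
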