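# Example pipeline configuration: an 8-patient phantom cohort on the
# default 64^3 grid, all stages enabled.
output_dir: results/run
master_seed: 20260927
n_patients: 8
stages:
  simulate: true
  petquant: true
  parcellate: true
  analyze: true
phantom:
  kappa: 0.5
  n_streamlines: 5000
stats:
  alpha_voxel: 0.001
  alpha_cluster: 0.05
  n_perm: 1000
  run_voxelwise: false
  outcome: aims_6m
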