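# Example pipeline configuration. Omitted keys keep the study-scale
# defaults (10000 permutations, 100000 posterior draws, 2.5-m lags,
# 0.5-m prediction raster, 90% CIs, alpha 0.05).
seed: 1
n_perm: 1000
n_draws: 10000
raster_res: 1.0
grid:
  phi_support: [0.5, 1, 2, 4, 8, 16, 25]
  tau2rel_support: [0, 0.1, 0.25, 0.5, 1]
domain:
  width: 40
  height: 50
truth:
  n_plants: 234
  n_env_sites: 71
  n_lines: 10
  dispersal_scale: 3
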