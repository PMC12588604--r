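# Desk-scale demo configuration: 20 x 30 grid cells over 0-60 N / 60-140 E,
# 3 species, 5000 checklists, seed 42. Every published analysis constant is a
# named key; omitted keys take the defaults of default_config().
seed: 42
grid:
  lat_min: 0
  lat_max: 60
  lon_min: 60
  lon_max: 140
  dlat: 3
  dlon: 2.6666667
n_species: 3
n_observers: 60
n_checklists: 5000
hotspot_bias: 1.5
n_individuals: 64
n_stopovers: 4
# checklist QC (printed rules)
max_distance_km: 3
min_duration_min: 5
max_duration_min: 300
min_expertise_pct: 2.5
hex_level: 7
# stixel ensemble (printed settings)
n_folds: 10
max_len: 25
min_len: 5
min_points: 50
window: 50
step: 20
coverage_min: 7
quantile_q: 0.1
# niche model
n_background: 10000
n_boot: 20
train_frac: 0.75
# Bayesian driver regressions (printed sampler settings)
chains: 4
tune: 3000
draws: 3000
rhat_max: 1.03
ess_min: 400
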