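# Demo pipeline profile: desk-scale virtual cohort on the packaged
# reference surrogate. The full-scale profile differs only in
# n_simulations (e.g. 120000).
model: packaged
n_simulations: 5000
master_seed: 4242
sampling: uniform
thresholds:
  normal_max: 1
  mild_lo: 5
  mild_hi: 10
screen_days: [7, 14, 21, 40]
evaluation_days: [14, 21]
n_bins: 50
cv_folds: 10
write_trajectories: false
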