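# Example pipeline configuration for padstress::run_pipeline().
# Omitted keys keep the package defaults (18 subjects, 8.17/3.75 ms
# sampling, 0.38 gap probability, areas 270.9/284.6 mm^2, ...).
generator:
  n_subjects: 6
  seed: 42
  gap_probability: 0.38
segmentation:
  max_gap_ms: 50
  max_jump_mm: 20
  min_stroke_samples: 4
grid_ms: 10
msd_method: covariance
alpha: 0.05
bonferroni_m: 3
scr_min_amplitude_uS: 0.01
write_event_logs: false
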