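# Example run configuration: desk-scale adversarial training on phantoms.
# Any key omitted here falls back to the package default (see run_config());
# unknown keys are rejected.
data:
  n_samples: 64
  volume_shape: [5, 64, 64]
  nodule_radius_range: [5.0, 12.0]
  nodule_kind: solid
  n_vessels: 3
preprocessing:
  roi_size: 32
generator:
  base_widths: [8, 16, 32, 64]
discriminator:
  widths: [8, 16, 32, 64]
training:
  batch_size: 8
  epochs: 19
  max_iters: 150
  seed: 42
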