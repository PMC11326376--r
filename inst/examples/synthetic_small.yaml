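# Small end-to-end example: simulate a two-section synthetic dataset,
# train on section 1, predict and evaluate on section 2.
simulate:
  enabled: true
  seed: 1
  n_rows: 16
  n_cols: 16
  spot_spacing_px: 64
  n_genes: 60
  n_latent: 4
  spatial_length_scale: 4
  image_encoding_strength: 1
  count_depth: 5000
  noise_dispersion: 2
  section_shift: 0.3
preprocess:
  patch_size: 64
  target_sum: 10000
  n_hvg: 50
  batch_correction: center_scale
  target_layer: corrected
train:
  epochs: 40
  batch_size: 128
  learning_rate: 0.003
  seed: 1
  use_sat: true
  use_backbone: true
  backbone_kind: tiny_cnn
  attention_scope: batch
eval:
  k_prime: 50
  rank_by: predicted
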