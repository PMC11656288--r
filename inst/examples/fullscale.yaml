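# Full-scale profile (GPU-class compute assumed; provided for completeness,
# not exercised by the CPU test suite): 2000 source epochs at SGD lr 5e-4 and batch size 1, six
# undertrained stops at epochs 30-80, a four-stage Refine model trained for
# 1000 epochs, and 200 adaptation iterations per test sample.
model:
  stages: 5
  encoder_channels: [16, 32, 64, 128, 256]
  proj_channels: 8
  sa_reduction: 2
wavelet:
  family: db2
  levels: 4
source:
  epochs: 2000
  learning_rate: 0.0005
  momentum: 0.9
  seed: 0
refine:
  depth: 4
  channels: [8, 16, 32, 64]
  epochs: 1000
  learning_rate: 0.0005
  schedule: [30, 40, 50, 60, 70, 80]
tta:
  iterations: 200
  learning_rate: 0.0005
  momentum: 0.9
  lambda1: 0.5
  lambda2: 1.0
  loss: total
data:
  # liver-profile preprocessing: 1.5 mm isotropic, 256x256x64, [0,1]
  extents: [256, 256, 64]
  target_spacing: [1.5, 1.5, 1.5]
  n_source: 15
  n_target: 20
  preset: strong
  seed: 0
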