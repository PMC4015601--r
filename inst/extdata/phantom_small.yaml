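# small synthetic phantom: one anisotropic facial blob in a 64 x 64 scene
frame_size: [64, 64]
background: 34.0
noise_sigma: 0.05
seed: 11
regions:
  - label: facial
    center: [32.5, 32.5]
    sigma: [6, 3]
    peak: 36.5
    theta: 0
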