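# tracking configuration for the bundled small phantom
matcher: ncc
window: 6
threshold: 50
patience: 10
tolerance_px: 2
calibration:
  emissivity: 0.972
  foil_transmission: 0.93
  ambient_temperature: 34.0
  registered_emissivity: 1.0
rois:
  - roi: face
    label: facial
    x: 17
    y: 17
    height: 32
    width: 32
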