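# Example configuration: every key shown with its default value.
image:
  calibration_default: 10.2
aponeurosis:
  threshold_method: otsu
  min_area_px: 100
  closing_radius: 3
fascicle:
  area_min_px: 75
  area_max_px: 6000
  eccentricity_min: 0.9
  adaptive_sensitivity: 0.5
  window_divisor: 8
  max_extrapolation_widths: 4
thickness:
  positions: [0.2, 0.5, 0.8]
  mode: vertical
reliability:
  loa_multiplier: 1.96
  conf_level: 0.95
seed: 1
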