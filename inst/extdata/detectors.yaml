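# Specifications of the three CsI(Tl) a-Si TFT flat-panel detectors.
# scintillator_thickness_factor is relative to the standard-thickness panel.
# pixel_pitch in micrometres, weight in kg.
FXRD-4343VAW:
  scintillator_thickness_factor: 1.0
  pixel_pitch: 140
  matrix: [3072, 3072]
  detection_area: [3048, 3048]
  weight: 3.45
FXRD-4343VAW Plus:
  scintillator_thickness_factor: 1.5
  pixel_pitch: 140
  matrix: [3072, 3072]
  detection_area: [3048, 3048]
  weight: 3.7
FXRD-4343FAW:
  scintillator_thickness_factor: 1.6
  pixel_pitch: 99
  matrix: [4316, 4316]
  detection_area: [4276, 4276]
  weight: 2.95
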