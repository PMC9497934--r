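# Standardized RQA beam qualities for flat-panel detector characterization.
# snr2_per_kerma is the squared SNR per air kerma in 1/(mm^2 uGy), numerically
# the photon fluence per mm^2 produced by 1 uGy of air kerma. The 2015
# protocol revision is the default; the superseded 2003 constants are kept as
# documented alternates.
"2015":
  RQA3:
    tube_voltage: 50
    added_filtration: 10.0
    half_value_layer: 3.8
    snr2_per_kerma: 21759
  RQA5:
    tube_voltage: 70
    added_filtration: 21.0
    half_value_layer: 6.8
    snr2_per_kerma: 20673
"2003":
  RQA3:
    tube_voltage: 50
    added_filtration: 10.0
    half_value_layer: 4.0
    snr2_per_kerma: 30174
  RQA5:
    tube_voltage: 70
    added_filtration: 21.0
    half_value_layer: 7.1
    snr2_per_kerma: 29653
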