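# CH-CDF boundary configuration.
# ch line: mean net charge R = ch_slope * mean scaled hydropathy H + ch_intercept
ch_slope: 2.785
ch_intercept: -1.151
hydropathy_window: 5
cdf_boundary:
  - [0.20, 0.25]
  - [0.30, 0.35]
  - [0.40, 0.45]
  - [0.50, 0.54]
  - [0.60, 0.63]
  - [0.70, 0.72]
  - [0.80, 0.80]
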