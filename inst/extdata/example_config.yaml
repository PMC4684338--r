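# Example pipeline configuration: simulate the default two-region phantom
# under the study acquisition protocol and analyse it end to end.
simulate: true
seed: 11
noise_sigma: 0.5          # additive Gaussian magnitude noise SD
protocol:
  tr: 4.0                 # ms
  flipDynamic: 15         # degrees
  flipT1map: 2            # degrees
  dt: 2.59                # s per dynamic
  nDynamics: 185
  injectionStart: 6       # s
r1: 4.5                   # 1/s/mM contrast relaxivity
hematocrit: 0.42
r2_threshold: 0.7         # goodness-of-fit filter for ROI statistics
min_roi_voxels: 5
cohort:
  simulate: true          # simulated per-site cohort for the outcome stage
  n_sf: 14
  n_sc: 19
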