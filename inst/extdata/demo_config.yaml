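# Demo: synthetic truth case on an overlapping prior, L-curve theta scan.
seed: 7
output_dir: saxsbme-demo
ensemble:
  synthetic:
    n_frames: 600
    n_residues: 60
    compaction: ~        # unbiased self-avoiding chain
saxs:
  synthetic:
    kappa: 0.15          # exponential tilt on R_g defining the truth, 1/A
    noise_level: 0.02    # fractional Gaussian noise on I(q)
theta:
  grid: {n_points: 16, min: 1, max: 1.0e+06}
scale_mode: scale+offset
density_bins: 40
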