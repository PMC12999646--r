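# Example msikit run configuration (values shown are the package defaults).
grid_shape: [120, 80]
spatial_resolution: 100     # um per pixel
n_healthy: 3
n_diseased: 4
scan_range: [200, 800]      # Th
noise:
  lognormal_sigma: 0.4      # per-pixel multiplicative noise, log scale
  ppm_jitter_sd: 0.8        # mass error SD, ppm
  replicate_offset_sd: 0.3  # per-replicate systematic offset SD, log2
  detection_floor: 10       # charges/s
  decoy_density: 5          # background peaks per 100 Th per pixel
fragmentation:
  survival_mid: 14          # % NCE at which half the precursor survives
  crossover_nce: 16         # % NCE where the two fragments are equal
lfc_threshold: 0.6
alpha: 0.05
tol_ppm: 5
roi:
  n_per_region: 10
  side: 3                   # pixels
scheme: replicate           # z-score scheme summarized in boxplots
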