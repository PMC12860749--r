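{
  "cohort": {
    "n_patients": 10,
    "grid_shape": [64, 64, 64],
    "voxel_spacing": [1, 1, 1],
    "noise_sd_hu": 10,
    "noise_sd_suv": 0.05,
    "treatment_effect": 0.8
  },
  "ct": {
    "radii_mm": [3, 4, 5, 6],
    "roi_shape": "disc",
    "interpretation": "density",
    "manual": true
  },
  "pet": {
    "erosion_mm": 2,
    "target_stat": "suv_max",
    "gap_score": 3
  },
  "panel": null,
  "alpha": 0.05,
  "seed": 42
}
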