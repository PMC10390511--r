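{
  "out_dir": "neuroload_out",
  "seed": 1,
  "simulate": {
    "n_participants": 20,
    "n_channels": 32,
    "fs": 250,
    "duration": 60,
    "effects": {
      "exponent_high": [-0.3, 0.1],
      "osc_theta_height": [0.15, 0.05],
      "osc_alpha_height": [-0.2, 0.07],
      "pac_m": [0.5, 0.1]
    },
    "baseline_sd": {
      "exponent_high": 0.15,
      "offset_high": 0.1,
      "exponent_low": 0.1,
      "offset_low": 0.1
    }
  },
  "preprocessing": {
    "target_fs": 250,
    "highpass_hz": 1,
    "epoch_s": 1
  },
  "bands": "statistics",
  "split": 25,
  "pac": {
    "channel": "Oz",
    "phase_freq": 9,
    "amp_band": [31, 90]
  },
  "stats": {
    "p_thresh": 0.01,
    "min_cluster": 4,
    "n_perm": 200
  }
}
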