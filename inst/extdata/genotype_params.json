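{
  "_comment": [
    "Calibration values for the synthetic-data generator.",
    "occupancy_pct rows are published group-mean vigilance-state",
    "percentages (W, N, R) per 12-h protocol window",
    "(BSL-L, BSL-D, SD-L, Rec-D1, Rec-L, Rec-D2); the loader renormalizes",
    "each row to sum to 1.  The SD-L row is documentary: sleep deprivation",
    "is simulated as forced wakefulness with the sd_leak probability.",
    "rebound_gain values are calibrated from published immediate delta",
    "rebound percentages (x/100); sd_band_gains from the published",
    "1.4- to 2.4-fold waking upper-theta increase during SD;",
    "icc_fraction from the published peak intraclass correlation (0.48).",
    "These are calibration constants, not claims about mechanism."
  ],
  "bout_scale": {
    "light": {"W": 65, "N": 60, "R": 25},
    "dark":  {"W": 250, "N": 48, "R": 16}
  },
  "homeostat": {"lower": 0.05, "upper": 1.0,
                "tau_rise_h": 8.0, "tau_decay_h": 1.5},
  "artifact_rate": 0.03,
  "icc_fraction": 0.48,
  "light_slope": 0.12,
  "genotypes": [
    {
      "label": "WT",
      "occupancy_pct": [
        [38.2, 46.8, 15.0],
        [77.9, 19.3, 2.8],
        [98.87, 1.13, 0.0],
        [58.0, 32.7, 9.4],
        [40.7, 44.5, 14.8],
        [73.3, 22.9, 3.9]
      ],
      "rebound_gain": 1.80,
      "sd_band_gains": {"upper_theta": 2.4, "beta2": 1.3, "gamma1": 1.3,
                        "tau_profile_h": 1.0},
      "tpf_hz": 7.08,
      "period_hr": 23.7,
      "sd_leak": 0.0113
    },
    {
      "label": "Per3-4/4",
      "occupancy_pct": [
        [38.7, 46.1, 15.2],
        [77.0, 20.1, 2.8],
        [99.20, 0.80, 0.0],
        [57.6, 32.3, 10.1],
        [41.2, 42.1, 16.8],
        [71.6, 23.9, 4.6]
      ],
      "rebound_gain": 1.6846,
      "sd_band_gains": {"upper_theta": 1.9, "beta2": 1.2, "gamma1": 1.2,
                        "tau_profile_h": 1.0},
      "tpf_hz": 7.08,
      "period_hr": 23.7,
      "sd_leak": 0.0080
    },
    {
      "label": "Per3-5/5",
      "occupancy_pct": [
        [40.9, 44.6, 14.4],
        [76.3, 20.6, 3.1],
        [99.16, 0.84, 0.0],
        [53.4, 36.4, 10.2],
        [42.3, 41.9, 15.8],
        [68.5, 26.4, 5.1]
      ],
      "rebound_gain": 1.9815,
      "sd_band_gains": {"upper_theta": 2.4, "beta2": 1.45, "gamma1": 1.45,
                        "tau_profile_h": 1.0},
      "tpf_hz": 6.84,
      "period_hr": 23.7,
      "sd_leak": 0.0084
    }
  ]
}
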