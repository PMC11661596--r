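{
  "normothermia_hypoxia": {
    "description": "Hypoxia (2% O2) at 37 C: gradual decline of firing and synchrony, complete loss of activity by 42 h; incomplete recovery.",
    "knots": {
      "t_h": [0, 42, 48],
      "mfr": [1.0, 0.0, 0.0],
      "nbr": [1.0, 0.0, 0.0],
      "nbd": [1.0, 0.3, 0.3]
    },
    "recovery_frac": { "mfr": 0.54, "nbr": 0.29, "nbd": 0.63 }
  },
  "hypothermia_hypoxia": {
    "description": "Hypoxia at 34 C: NBR drops to ~50% by 2 h, stable plateau to 34 h, then declines until all synchronous events cease at 48 h; MFR and NBD decline gradually. Recovery NBR 1.7-fold above baseline (recovery MFR/NBD multipliers are not reported and are package choices).",
    "knots": {
      "t_h": [0, 2, 34, 48],
      "mfr": [1.0, 0.9, 0.35, 0.05],
      "nbr": [1.0, 0.5, 0.5, 0.0],
      "nbd": [1.0, 0.95, 0.55, 0.3]
    },
    "recovery_frac": { "mfr": 1.0, "nbr": 1.7, "nbd": 0.9 }
  },
  "hyperthermia_hypoxia": {
    "description": "Hypoxia at 39 C: MFR elevated for the first 14 h; NBR rises 1.5-fold and stays elevated for 24 h, then drops and disappears by 42 h; NBD declines gradually. Recovery: minimal firing, no network bursts.",
    "knots": {
      "t_h": [0, 2, 14, 24, 42, 48],
      "mfr": [1.0, 1.2, 1.2, 0.77, 0.0, 0.0],
      "nbr": [1.0, 1.5, 1.5, 1.5, 0.0, 0.0],
      "nbd": [1.0, 0.97, 0.8, 0.65, 0.39, 0.3]
    },
    "recovery_frac": { "mfr": 0.1, "nbr": 0.0, "nbd": 0.3 }
  },
  "hypothermia_normoxia": {
    "description": "Normoxia at 34 C: gradual decline of MFR/NBR/NBD over 48 h; after rewarming MFR reaches only 31% of baseline and network bursts remain absent.",
    "knots": {
      "t_h": [0, 48],
      "mfr": [1.0, 0.2],
      "nbr": [1.0, 0.15],
      "nbd": [1.0, 0.4]
    },
    "recovery_frac": { "mfr": 0.31, "nbr": 0.0, "nbd": 0.5 }
  },
  "hyperthermia_normoxia": {
    "description": "Normoxia at 39 C: gradual decline of MFR/NBR/NBD over 48 h; after return to 37 C MFR reaches 28% and NBR only 7% of baseline.",
    "knots": {
      "t_h": [0, 48],
      "mfr": [1.0, 0.2],
      "nbr": [1.0, 0.15],
      "nbd": [1.0, 0.4]
    },
    "recovery_frac": { "mfr": 0.28, "nbr": 0.07, "nbd": 0.5 }
  },
  "control_normoxia": {
    "description": "Normoxia at 37 C throughout: stationary activity (null condition for calibration tests).",
    "knots": {
      "t_h": [0, 48],
      "mfr": [1.0, 1.0],
      "nbr": [1.0, 1.0],
      "nbd": [1.0, 1.0]
    },
    "recovery_frac": { "mfr": 1.0, "nbr": 1.0, "nbd": 1.0 }
  }
}
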