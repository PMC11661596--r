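{
  "_comment": "Analysis constants of the assay, exposed in one versioned place for auditability.",
  "sampling_rate_hz": 10000,
  "highpass": { "order": 2, "cutoff_hz": 100 },
  "lowpass": { "order": 4, "cutoff_hz": 3500 },
  "spike_threshold_sd": 5,
  "active_rate_min_hz": 0.1,
  "burst_min_spikes": 4,
  "burst_max_isi_ms": 50,
  "burst_min_interval_ms": 100,
  "bursting_channel_min_per_min": 0.4,
  "network_burst_min_channels": 6,
  "network_burst_min_concurrent": 4,
  "inclusion_mfr_hz": 0.1,
  "inclusion_nbr_per_min": 1,
  "rout_q": 0.01,
  "star_cutpoints": [0.05, 0.005, 0.0005, 0.0001]
}
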