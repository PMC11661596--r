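{
  "_comment": "Synapsin1/2 puncta per 10 um of MAP2-positive neurite. Baseline is a package choice of a realistic absolute density; hypoxia-phase normothermia values encode the reported 32/20/50% losses relative to baseline, hyperthermia mirrors normothermia, hypothermia-during-hypoxia is above baseline (magnitude unreported). Recovery densities are as printed.",
  "baseline": 1.2,
  "normothermia_6h":  0.816,
  "normothermia_24h": 0.96,
  "normothermia_48h": 0.6,
  "hypothermia_6h":   1.5,
  "hypothermia_24h":  1.5,
  "hypothermia_48h":  1.5,
  "hyperthermia_6h":  0.816,
  "hyperthermia_24h": 0.96,
  "hyperthermia_48h": 0.6,
  "normothermia_rec6":  0.84,
  "hypothermia_rec6":   0.99,
  "normothermia_rec24": 0.8,
  "hypothermia_rec24":  1.6
}
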