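{
  "_comment": "Percent composition (live / apoptotic / dead / unclassified) of cultures per condition and fixation timepoint. Values are renormalised to 1 by the generator. Entries marked inferred fill gaps the source figures leave (stacked bars report only some classes); 'unclassified' (DAPI+PI without CellEvent) is a 1% floor. hypothermia_rec24 live is as printed; the printed apoptotic 16% is inconsistent with it (sum > 100) and is replaced by the remainder.",
  "baseline_normoxia":   { "live": 90, "apoptotic": 6,  "dead": 3,  "unclassified": 1 },
  "normothermia_24h":    { "live": 36, "apoptotic": 11, "dead": 52, "unclassified": 1 },
  "hypothermia_24h":     { "live": 48, "apoptotic": 19, "dead": 34, "unclassified": 1 },
  "hyperthermia_24h":    { "live": 34, "apoptotic": 10, "dead": 56, "unclassified": 1 },
  "normothermia_48h":    { "live": 55, "apoptotic": 13, "dead": 32, "unclassified": 1 },
  "hypothermia_48h":     { "live": 61, "apoptotic": 17, "dead": 22, "unclassified": 1 },
  "hyperthermia_48h":    { "live": 33, "apoptotic": 4,  "dead": 63, "unclassified": 1 },
  "normothermia_rec6":   { "live": 62, "apoptotic": 14, "dead": 23, "unclassified": 1 },
  "hypothermia_rec6":    { "live": 55, "apoptotic": 20, "dead": 24, "unclassified": 1 },
  "normothermia_rec24":  { "live": 37, "apoptotic": 49, "dead": 13, "unclassified": 1 },
  "hypothermia_rec24":   { "live": 93, "apoptotic": 4,  "dead": 2,  "unclassified": 1 }
}
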