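{
  "rc_core": ["pufL", "pufM"],
  "bch_entries": [
    ["bchB"], ["bchC"], ["bchD"], ["bchE", "acsF"], ["bchF"], ["bchG"],
    ["bchH"], ["bchI"], ["bchL"], ["bchM"], ["bchN"], ["bchP"],
    ["bchX"], ["bchY"], ["bchZ"]
  ],
  "bch_min": 4,
  "lh2_families": ["pucA", "pucB"],
  "carotenoid_families": ["crtC", "crtD", "crtF"],
  "cbb": {
    "name": "Calvin-Benson-Bassham cycle",
    "steps": [
      {"name": "rubisco", "alternatives": [["cbbL", "cbbS"]], "required": true},
      {"name": "phosphoglycerate_kinase", "alternatives": [["pgk"], ["cbbK"]]},
      {"name": "gapdh", "alternatives": [["cbbG"], ["gapA"]]},
      {"name": "triosephosphate_isomerase", "alternatives": [["tpiA"]]},
      {"name": "fbp_aldolase", "alternatives": [["cbbA"], ["fbaA"]]},
      {"name": "fbp_sbp_phosphatase", "alternatives": [["cbbF"], ["glpX"], ["fbp"]]},
      {"name": "transketolase", "alternatives": [["cbbT"], ["tktA"]]},
      {"name": "ru5p_epimerase", "alternatives": [["cbbE"], ["rpe"]]},
      {"name": "r5p_isomerase", "alternatives": [["cbbI"], ["rpiA"]]},
      {"name": "phosphoribulokinase", "alternatives": [["cbbP"], ["prkB"]]}
    ]
  }
}
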