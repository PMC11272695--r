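{
  "label": "best_overall",
  "lipophilicity_sources": ["BayerLogD", "BayerLogMA"],
  "lipophilicity_consensus": true,
  "lipophilicity_conversion": null,
  "pka_source": "ChemAxon",
  "partitioning_method": "pksim_standard",
  "fu_source": "measured",
  "clearance_source": "in vivo",
  "clearance_mode": "plasma",
  "renal_passive": false,
  "solubility_source": "SimPlus",
  "solubility_subtype": "FaSSIF",
  "permeability_source": "ADMETLab",
  "permeability_subtype": "MDCK",
  "permeability_scaling": "direct",
  "permeability_scale_factor": 1.0
}
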