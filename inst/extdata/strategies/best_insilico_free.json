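{
  "label": "best_insilico_free",
  "lipophilicity_sources": ["ADMETLab"],
  "lipophilicity_consensus": false,
  "lipophilicity_conversion": null,
  "pka_source": "none",
  "partitioning_method": "pksim_standard",
  "fu_source": "ADMETLab",
  "clearance_source": "ADMETLab",
  "clearance_mode": "plasma",
  "renal_passive": false,
  "solubility_source": "ADMETLab",
  "solubility_subtype": "aqueous",
  "permeability_source": "ADMETLab",
  "permeability_subtype": "MDCK",
  "permeability_scaling": "direct",
  "permeability_scale_factor": 1.0
}
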