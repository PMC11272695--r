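{
  "organs": {
    "name": ["venous_blood", "arterial_blood", "lung", "liver", "kidney", "gut", "spleen", "muscle", "adipose", "skin", "brain", "heart", "bone", "rest"],
    "volume_L": [3.9, 1.7, 0.5, 1.8, 0.31, 1.1, 0.15, 29, 13.5, 3.3, 1.45, 0.33, 10.3, 2.5],
    "flow_L_h": [0, 0, 390, 25.35, 74.1, 58.5, 11.7, 66.3, 19.5, 19.5, 46.8, 15.6, 19.5, 33.15],
    "eliminating": [false, false, false, true, true, false, false, false, false, false, false, false, false, false],
    "f_water": [0.945, 0.945, 0.782, 0.734, 0.756, 0.757, 0.786, 0.748, 0.152, 0.673, 0.782, 0.776, 0.446, 0.72],
    "f_neutral_lipid": [0.0023, 0.0023, 0.003, 0.035, 0.021, 0.049, 0.02, 0.024, 0.79, 0.028, 0.051, 0.012, 0.017, 0.04],
    "f_phospholipid": [0.0013, 0.0013, 0.009, 0.0252, 0.0162, 0.0163, 0.0198, 0.0072, 0.0016, 0.0111, 0.0565, 0.0166, 0.0017, 0.012],
    "f_protein": [0.05, 0.05, 0.15, 0.18, 0.16, 0.15, 0.15, 0.19, 0.02, 0.25, 0.08, 0.16, 0.2, 0.17],
    "f_acidic_phospholipid": [4e-05, 4e-05, 0.00391, 0.00456, 0.00503, 0.00241, 0.00318, 0.00153, 0.0004, 0.00132, 0.0004, 0.00225, 0.00067, 0.002]
  },
  "GFR_L_h": 7.2,
  "hepatocellularity_cells_g": 110000000,
  "liver_density_g_ml": 1.05,
  "body_weight_kg": 73,
  "demographics": {
    "sex": "male",
    "age": 30,
    "weight": 73,
    "height": 176
  }
}
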