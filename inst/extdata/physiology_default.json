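{
  "description": "Reference adult European male, 73 kg. Reduced whole-body physiology: venous/arterial blood, gut lumen, gut wall (intestinal mucosa), liver, kidney, lumped rest-of-body. Volumes in L, plasma-equivalent flows in L/h. Enzyme concentrations in umol per L organ tissue (relative scale; catalytic constants are calibrated against it). kdeg in 1/h.",
  "body_weight_kg": 73,
  "gfr_L_per_h": 7.2,
  "cyp2c19_phenotype": "NM",
  "organs": [
    {"name": "venous_blood",   "volume_L": 3.6,  "flow_L_per_h": 0,   "kp": 1},
    {"name": "arterial_blood", "volume_L": 1.8,  "flow_L_per_h": 0,   "kp": 1},
    {"name": "gut_lumen",      "volume_L": 1.0,  "flow_L_per_h": 0,   "kp": 1},
    {"name": "gut_wall",       "volume_L": 1.1,  "flow_L_per_h": 46,  "kp": 1},
    {"name": "liver",          "volume_L": 2.1,  "flow_L_per_h": 20,  "kp": 1},
    {"name": "kidney",         "volume_L": 0.31, "flow_L_per_h": 70,  "kp": 1},
    {"name": "rest",           "volume_L": 64.1, "flow_L_per_h": 176, "kp": 1}
  ],
  "expressions": [
    {"enzyme": "CES1",    "organ": "liver",    "conc_umol_per_L": 5.0},
    {"enzyme": "CES2",    "organ": "gut_wall", "conc_umol_per_L": 4.0},
    {"enzyme": "UGT2B7",  "organ": "liver",    "conc_umol_per_L": 3.0},
    {"enzyme": "UGT2B7",  "organ": "kidney",   "conc_umol_per_L": 0.6},
    {"enzyme": "CYP2C19", "organ": "liver",    "conc_umol_per_L": 0.76},
    {"enzyme": "CYP2C19", "organ": "gut_wall", "conc_umol_per_L": 0.30},
    {"enzyme": "CYP3A4",  "organ": "liver",    "conc_umol_per_L": 4.32},
    {"enzyme": "CYP3A4",  "organ": "gut_wall", "conc_umol_per_L": 1.20},
    {"enzyme": "CYP2B6",  "organ": "liver",    "conc_umol_per_L": 0.54},
    {"enzyme": "CYP2C8",  "organ": "liver",    "conc_umol_per_L": 2.56}
  ],
  "kdeg_per_h": {
    "CES1": 0.03, "CES2": 0.03, "UGT2B7": 0.03,
    "CYP2C19": 0.026, "CYP3A4": 0.019, "CYP2B6": 0.032, "CYP2C8": 0.062
  }
}
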