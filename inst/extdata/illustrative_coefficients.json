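{
  "betas": {
    "pc": {
      "age_c": 0.03,
      "lpsa": 0.35,
      "gg2": 0.55,
      "gg3": 1.05,
      "gg4": 1.55,
      "gg5": 2.15,
      "t2": 0.35,
      "t3": 0.85,
      "t4": 1.3,
      "ppc": 0.9
    },
    "npc": {
      "age_c": 0.09,
      "comorb": 0.65
    }
  },
  "transforms": {
    "age_c": {
      "variable": "age_dx",
      "type": "identity",
      "center": 65
    },
    "lpsa": {
      "variable": "psa",
      "type": "log",
      "center": 2.30258509299405
    },
    "gg2": {
      "variable": "grade_group",
      "type": "indicator",
      "level": 2
    },
    "gg3": {
      "variable": "grade_group",
      "type": "indicator",
      "level": 3
    },
    "gg4": {
      "variable": "grade_group",
      "type": "indicator",
      "level": 4
    },
    "gg5": {
      "variable": "grade_group",
      "type": "indicator",
      "level": 5
    },
    "t2": {
      "variable": "t_stage",
      "type": "indicator",
      "level": "T2"
    },
    "t3": {
      "variable": "t_stage",
      "type": "indicator",
      "level": "T3"
    },
    "t4": {
      "variable": "t_stage",
      "type": "indicator",
      "level": "T4"
    },
    "comorb": {
      "variable": "comorbid",
      "type": "indicator",
      "level": true
    },
    "ppc": {
      "variable": "ppc",
      "type": "ppc"
    }
  },
  "baseline_hazard": {
    "pc": [0.00374, 0.00398, 0.00422, 0.00446, 0.0047, 0.00494, 0.00518, 0.00542, 0.00566, 0.0059, 0.00614, 0.00638, 0.00662, 0.00686, 0.0071],
    "npc": [0.0129, 0.013545, 0.01422225, 0.0149333625, 0.015680030625, 0.01646403215625, 0.0172872337640625, 0.0181515954522656, 0.0190591752248789, 0.0200121339861229, 0.021012740685429, 0.0220633777197005, 0.0231665466056855, 0.0243248739359698, 0.0255411176327682]
  },
  "radical_hr_pc": 0.65,
  "ppc_mode": "excluded",
  "adt_hr_pc": 1
}
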