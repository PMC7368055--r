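{
  "schema_version": "1.0",
  "microspots": {
    "M1": {
      "id": "M1",
      "label": "BSA control",
      "coating": [{"component": "BSA blocking buffer", "value": 1, "unit": "%"}],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": [],
      "tf_in_medium": false
    },
    "M2": {
      "id": "M2",
      "label": "rhodocytin + VWF",
      "coating": [
        {"component": "rhodocytin", "value": 250, "unit": "ug/mL"},
        {"component": "VWF", "value": 50, "unit": "ug/mL"}
      ],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "CLEC2"],
      "tf_in_medium": false
    },
    "M3": {
      "id": "M3",
      "label": "laminin + VWF",
      "coating": [
        {"component": "laminin", "value": 100, "unit": "ug/mL"},
        {"component": "VWF", "value": 50, "unit": "ug/mL"}
      ],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "a6b1"],
      "tf_in_medium": false
    },
    "M4": {
      "id": "M4",
      "label": "collagen-III (binds plasma VWF)",
      "coating": [{"component": "collagen-III", "value": 100, "unit": "ug/mL"}],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": false
    },
    "M5": {
      "id": "M5",
      "label": "collagen-I low (binds plasma VWF)",
      "coating": [{"component": "collagen-I", "value": 10, "unit": "ug/mL"}],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": false
    },
    "M6": {
      "id": "M6",
      "label": "collagen-I high (binds plasma VWF)",
      "coating": [{"component": "collagen-I", "value": 50, "unit": "ug/mL"}],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": false
    },
    "M7": {
      "id": "M7",
      "label": "GFOGER-(GPO)n + VWF-BP",
      "coating": [
        {"component": "GFOGER-GPO", "value": 250, "unit": "ug/mL"},
        {"component": "VWF-BP", "value": 100, "unit": "ug/mL"}
      ],
      "co_coating": "TF",
      "co_coating_max": {"value": 500, "unit": "pM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": false
    },
    "M8": {
      "id": "M8",
      "label": "collagen-I + TM",
      "coating": [{"component": "collagen-I", "value": 50, "unit": "ug/mL"}],
      "co_coating": "TM",
      "co_coating_max": {"value": 10, "unit": "nM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": true,
      "tf_in_medium_dose": {"value": 10, "unit": "pM"}
    },
    "M9": {
      "id": "M9",
      "label": "collagen-I + APC",
      "coating": [{"component": "collagen-I", "value": 50, "unit": "ug/mL"}],
      "co_coating": "APC",
      "co_coating_max": {"value": 10, "unit": "nM"},
      "receptors": ["GPIb", "GPVI", "a2b1"],
      "tf_in_medium": true,
      "tf_in_medium_dose": {"value": 10, "unit": "pM"}
    }
  },
  "parameters": {
    "P1": {"id": "P1", "label": "Platelet adhesion", "channel": "platelet", "unit": "%SAC", "range": [0, 100], "times_min": [0, 2, 4, 6, 8], "group": "platelet"},
    "P2": {"id": "P2", "label": "Platelet PS exposure", "channel": "ps", "unit": "%SAC", "range": [0, 100], "times_min": [0, 2, 4, 6, 8], "group": "platelet"},
    "P3": {"id": "P3", "label": "Thrombus coverage", "channel": "brightfield", "unit": "%SAC", "range": [0, 100], "times_min": [0, 2, 4, 6, 8], "group": "thrombus"},
    "P4": {"id": "P4", "label": "Thrombus morphology score", "channel": "brightfield", "unit": "score", "range": [0, 5], "times_min": [0, 2, 4, 6, 8], "group": "thrombus"},
    "P5": {"id": "P5", "label": "Thrombus aggregation score", "channel": "brightfield", "unit": "score", "range": [0, 3], "times_min": [0, 2, 4, 6, 8], "group": "thrombus"},
    "P6": {"id": "P6", "label": "Thrombus contraction score", "channel": "brightfield", "unit": "score", "range": [0, 3], "times_min": [0, 2, 4, 6, 8], "group": "thrombus"},
    "P7": {"id": "P7", "label": "Fibrin deposition", "channel": "fibrin", "unit": "%SAC", "range": [0, 100], "times_min": [0, 2, 4, 6, 8], "group": "fibrin"},
    "P8": {"id": "P8", "label": "Fibrin score", "channel": "brightfield", "unit": "score", "range": [0, 3], "times_min": [0, 2, 4, 6, 8], "group": "fibrin"},
    "P9": {"id": "P9", "label": "Shorter time to fibrin", "channel": "fibrin", "unit": "11 - t min", "range": [0, 11], "times_min": [0, 2, 4, 6, 8, 10], "group": "fibrin"}
  },
  "curve_characteristics": {
    "C1": {"id": "C1", "label": "Shorter time to first thrombin", "unit": "min"},
    "C2": {"id": "C2", "label": "Endogenous thrombin potential (ETP)", "unit": "nM min"},
    "C3": {"id": "C3", "label": "Thrombin peak", "unit": "nM"}
  }
}
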