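{
  "points": [
    {
      "name": "age",
      "values": [
        45,
        60,
        75
      ]
    },
    {
      "name": "pt_stage",
      "values": [
        "T1",
        "T2",
        "T3",
        "T4"
      ]
    },
    {
      "name": "pn_stage",
      "values": [
        "N0",
        "N1",
        "N2"
      ]
    },
    {
      "name": "nodes_examined",
      "values": [
        "LT10",
        "GE10"
      ]
    },
    {
      "name": "differentiation",
      "values": [
        "WELL_MODERATE",
        "POOR_UNDIFF"
      ]
    },
    {
      "name": "vascular_invasion",
      "values": [
        false,
        true
      ]
    },
    {
      "name": "obstruction_or_perforation",
      "values": [
        false,
        true
      ]
    },
    {
      "name": "msi_status",
      "values": [
        "MSS",
        "MSI"
      ]
    },
    {
      "name": "oxaliplatin_contraindicated",
      "values": [
        false,
        true
      ]
    },
    {
      "name": "serious_liver_disease",
      "values": [
        false,
        true
      ]
    },
    {
      "name": "serious_kidney_disease",
      "values": [
        false,
        true
      ]
    },
    {
      "name": "resection_margin",
      "constant": "NEGATIVE"
    },
    {
      "name": "perineural_invasion",
      "constant": false
    },
    {
      "name": "functional_status",
      "constant": 0
    }
  ],
  "mode": "FULL_FACTORIAL",
  "guideline_point_names": [
    "age",
    "pt_stage",
    "pn_stage",
    "nodes_examined",
    "differentiation",
    "vascular_invasion",
    "obstruction_or_perforation",
    "msi_status",
    "oxaliplatin_contraindicated"
  ],
  "advisor_point_names": [
    "age",
    "pt_stage",
    "pn_stage",
    "nodes_examined",
    "differentiation",
    "vascular_invasion",
    "obstruction_or_perforation",
    "msi_status",
    "serious_liver_disease",
    "serious_kidney_disease",
    "resection_margin",
    "perineural_invasion",
    "functional_status"
  ]
}
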