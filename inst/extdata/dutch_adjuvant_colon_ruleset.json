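{
  "name": "dutch_adjuvant_colon",
  "root": "pn",
  "nodes": {
    "pn": {
      "field": "pn_stage",
      "edges": [
        {
          "values": [
            "N0"
          ],
          "target": "pt"
        },
        {
          "values": [
            "N1",
            "N2"
          ],
          "target": "s3_oxa"
        }
      ]
    },
    "pt": {
      "field": "pt_stage",
      "edges": [
        {
          "values": [
            "T1",
            "T2"
          ],
          "target": "leaf_obs"
        },
        {
          "values": [
            "T3"
          ],
          "target": "s2_nodes"
        },
        {
          "values": [
            "T4"
          ],
          "target": "s2_msi"
        }
      ]
    },
    "s2_nodes": {
      "field": "nodes_examined",
      "edges": [
        {
          "values": [
            "LT10"
          ],
          "target": "s2_msi"
        },
        {
          "values": [
            "GE10"
          ],
          "target": "s2_diff"
        }
      ]
    },
    "s2_diff": {
      "field": "differentiation",
      "edges": [
        {
          "values": [
            "POOR_UNDIFF"
          ],
          "target": "s2_msi"
        },
        {
          "values": [
            "WELL_MODERATE"
          ],
          "target": "s2_vasc"
        }
      ]
    },
    "s2_vasc": {
      "field": "vascular_invasion",
      "edges": [
        {
          "values": [
            "TRUE"
          ],
          "target": "s2_msi"
        },
        {
          "values": [
            "FALSE"
          ],
          "target": "s2_obstr"
        }
      ]
    },
    "s2_obstr": {
      "field": "obstruction_or_perforation",
      "edges": [
        {
          "values": [
            "TRUE"
          ],
          "target": "s2_msi"
        },
        {
          "values": [
            "FALSE"
          ],
          "target": "leaf_obs"
        }
      ]
    },
    "s2_msi": {
      "field": "msi_status",
      "edges": [
        {
          "values": [
            "MSI"
          ],
          "target": "leaf_obs"
        },
        {
          "values": [
            "MSS"
          ],
          "target": "s2_oxa"
        }
      ]
    },
    "s2_oxa": {
      "field": "oxaliplatin_contraindicated",
      "edges": [
        {
          "values": [
            "TRUE"
          ],
          "target": "leaf_obs"
        },
        {
          "values": [
            "FALSE"
          ],
          "target": "leaf_consider_doublet"
        }
      ]
    },
    "s3_oxa": {
      "field": "oxaliplatin_contraindicated",
      "edges": [
        {
          "values": [
            "FALSE"
          ],
          "target": "leaf_doublet"
        },
        {
          "values": [
            "TRUE"
          ],
          "target": "s3_msi"
        }
      ]
    },
    "s3_msi": {
      "field": "msi_status",
      "edges": [
        {
          "values": [
            "MSS"
          ],
          "target": "leaf_mono"
        },
        {
          "values": [
            "MSI"
          ],
          "target": "leaf_obs"
        }
      ]
    },
    "leaf_obs": {
      "advice": {
        "OBSERVATION": "R"
      }
    },
    "leaf_consider_doublet": {
      "advice": {
        "OBSERVATION": "R",
        "CAPOX": "C",
        "FOLFOX": "C"
      }
    },
    "leaf_doublet": {
      "advice": {
        "CAPOX": "R",
        "FOLFOX": "R"
      }
    },
    "leaf_mono": {
      "advice": {
        "CAPE_MONO": "R",
        "FU_LV_MONO": "R"
      }
    }
  }
}
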