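{
  "name": "nccn_style_template_synthetic",
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
          "target": "leaf_doublet"
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
            "T3",
            "T4"
          ],
          "target": "s2_msi"
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
          "target": "leaf_consider"
        }
      ]
    },
    "leaf_obs": {
      "advice": {
        "OBSERVATION": "R"
      }
    },
    "leaf_consider": {
      "advice": {
        "OBSERVATION": "R",
        "CAPOX": "C",
        "FOLFOX": "C",
        "CAPE_MONO": "C",
        "FU_LV_MONO": "C"
      }
    },
    "leaf_doublet": {
      "advice": {
        "CAPOX": "R",
        "FOLFOX": "R",
        "CAPE_MONO": "C",
        "FU_LV_MONO": "C"
      }
    }
  }
}
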