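{
  "schema_version": 1,
  "horizon_years": 5,
  "female": {
    "baseline_survival": 0.979,
    "terms": [
      {
        "name": "age",
        "source": "age_at_index",
        "coefficient": 0.078,
        "center": 55,
        "transform": "identity"
      },
      {
        "name": "sbp",
        "coefficient": 0.012,
        "center": 128,
        "transform": "identity",
        "source": "sbp"
      },
      {
        "name": "tchdl",
        "coefficient": 0.16,
        "center": 3.8,
        "transform": "identity",
        "source": "tchdl"
      },
      {
        "name": "smoker_past",
        "transform": "indicator",
        "source": "smoker_status",
        "level": "past",
        "coefficient": 0.12,
        "center": 0
      },
      {
        "name": "smoker_current",
        "transform": "indicator",
        "source": "smoker_status",
        "level": "current",
        "coefficient": 0.6,
        "center": 0
      },
      {
        "name": "diabetes",
        "coefficient": 0.5,
        "center": 0,
        "transform": "identity",
        "source": "diabetes"
      },
      {
        "name": "atrial_fibrillation",
        "coefficient": 0.9,
        "center": 0,
        "transform": "identity",
        "source": "atrial_fibrillation"
      },
      {
        "name": "family_history",
        "coefficient": 0.15,
        "center": 0,
        "transform": "identity",
        "source": "family_history"
      },
      {
        "name": "eth_maori",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Maori",
        "coefficient": 0.3,
        "center": 0
      },
      {
        "name": "eth_pacific",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Pacific",
        "coefficient": 0.25,
        "center": 0
      },
      {
        "name": "eth_indian",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Indian",
        "coefficient": 0.35,
        "center": 0
      },
      {
        "name": "eth_asian",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Chinese/other Asian",
        "coefficient": -0.25,
        "center": 0
      },
      {
        "name": "dep_q2",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "2",
        "coefficient": 0.05,
        "center": 0
      },
      {
        "name": "dep_q3",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "3",
        "coefficient": 0.1,
        "center": 0
      },
      {
        "name": "dep_q4",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "4",
        "coefficient": 0.15,
        "center": 0
      },
      {
        "name": "dep_q5",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "5",
        "coefficient": 0.25,
        "center": 0
      },
      {
        "name": "bp_lowering",
        "coefficient": 0.25,
        "center": 0,
        "transform": "identity",
        "source": "bp_lowering"
      },
      {
        "name": "lipid_lowering",
        "coefficient": 0.1,
        "center": 0,
        "transform": "identity",
        "source": "lipid_lowering"
      },
      {
        "name": "antithrombotic",
        "coefficient": 0.15,
        "center": 0,
        "transform": "identity",
        "source": "antithrombotic"
      }
    ],
    "interactions": []
  },
  "male": {
    "baseline_survival": 0.968,
    "terms": [
      {
        "name": "age",
        "source": "age_at_index",
        "coefficient": 0.07,
        "center": 55,
        "transform": "identity"
      },
      {
        "name": "sbp",
        "coefficient": 0.012,
        "center": 128,
        "transform": "identity",
        "source": "sbp"
      },
      {
        "name": "tchdl",
        "coefficient": 0.16,
        "center": 4.4,
        "transform": "identity",
        "source": "tchdl"
      },
      {
        "name": "smoker_past",
        "transform": "indicator",
        "source": "smoker_status",
        "level": "past",
        "coefficient": 0.12,
        "center": 0
      },
      {
        "name": "smoker_current",
        "transform": "indicator",
        "source": "smoker_status",
        "level": "current",
        "coefficient": 0.5,
        "center": 0
      },
      {
        "name": "diabetes",
        "coefficient": 0.5,
        "center": 0,
        "transform": "identity",
        "source": "diabetes"
      },
      {
        "name": "atrial_fibrillation",
        "coefficient": 0.9,
        "center": 0,
        "transform": "identity",
        "source": "atrial_fibrillation"
      },
      {
        "name": "family_history",
        "coefficient": 0.15,
        "center": 0,
        "transform": "identity",
        "source": "family_history"
      },
      {
        "name": "eth_maori",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Maori",
        "coefficient": 0.3,
        "center": 0
      },
      {
        "name": "eth_pacific",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Pacific",
        "coefficient": 0.25,
        "center": 0
      },
      {
        "name": "eth_indian",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Indian",
        "coefficient": 0.35,
        "center": 0
      },
      {
        "name": "eth_asian",
        "transform": "indicator",
        "source": "ethnicity",
        "level": "Chinese/other Asian",
        "coefficient": -0.25,
        "center": 0
      },
      {
        "name": "dep_q2",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "2",
        "coefficient": 0.05,
        "center": 0
      },
      {
        "name": "dep_q3",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "3",
        "coefficient": 0.1,
        "center": 0
      },
      {
        "name": "dep_q4",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "4",
        "coefficient": 0.15,
        "center": 0
      },
      {
        "name": "dep_q5",
        "transform": "indicator",
        "source": "deprivation_quintile",
        "level": "5",
        "coefficient": 0.25,
        "center": 0
      },
      {
        "name": "bp_lowering",
        "coefficient": 0.25,
        "center": 0,
        "transform": "identity",
        "source": "bp_lowering"
      },
      {
        "name": "lipid_lowering",
        "coefficient": 0.1,
        "center": 0,
        "transform": "identity",
        "source": "lipid_lowering"
      },
      {
        "name": "antithrombotic",
        "coefficient": 0.15,
        "center": 0,
        "transform": "identity",
        "source": "antithrombotic"
      }
    ],
    "interactions": []
  }
}
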