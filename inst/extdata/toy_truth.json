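{
  "seed": 101,
  "baseline": 8,
  "noise_sd": 1,
  "shifts": {
    "control": {
      "pathway_shifts": {
        "P1": 3,
        "P3": -3
      },
      "gene_shifts": []
    },
    "disease": {
      "pathway_shifts": {
        "P1": -3,
        "P3": 3
      },
      "gene_shifts": []
    }
  },
  "decreased_pathways": "P1",
  "implanted_biomarkers": [
    {
      "metabolite": "m_1_0",
      "direction": "uptake_decrease"
    },
    {
      "metabolite": "m_1_4",
      "direction": "secretion_decrease"
    },
    {
      "metabolite": "m_3_0",
      "direction": "uptake_increase"
    },
    {
      "metabolite": "m_3_4",
      "direction": "secretion_increase"
    }
  ],
  "decoy_exchanges": ["m_2_0", "m_2_4", "m_4_0", "m_4_4"]
}
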