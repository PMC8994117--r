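{
  "name": "men",
  "nodes": [
    {
      "id": "M1_L",
      "hemisphere": "L",
      "region": "M1"
    },
    {
      "id": "PMd_L",
      "hemisphere": "L",
      "region": "PMd"
    },
    {
      "id": "PMd_R",
      "hemisphere": "R",
      "region": "PMd"
    },
    {
      "id": "PMv_L",
      "hemisphere": "L",
      "region": "PMv"
    },
    {
      "id": "PMv_R",
      "hemisphere": "R",
      "region": "PMv"
    },
    {
      "id": "SPL_L",
      "hemisphere": "L",
      "region": "SPL"
    },
    {
      "id": "SPL_R",
      "hemisphere": "R",
      "region": "SPL"
    },
    {
      "id": "BG_L",
      "hemisphere": "L",
      "region": "BG"
    },
    {
      "id": "BG_R",
      "hemisphere": "R",
      "region": "BG"
    },
    {
      "id": "Thal_L",
      "hemisphere": "L",
      "region": "Thal"
    },
    {
      "id": "Thal_R",
      "hemisphere": "R",
      "region": "Thal"
    },
    {
      "id": "aiCereb_L",
      "hemisphere": "L",
      "region": "aiCereb"
    },
    {
      "id": "aiCereb_R",
      "hemisphere": "R",
      "region": "aiCereb"
    },
    {
      "id": "PoG_L",
      "hemisphere": "L",
      "region": "PoG"
    },
    {
      "id": "PoG_R",
      "hemisphere": "R",
      "region": "PoG"
    },
    {
      "id": "Dentate_L",
      "hemisphere": "L",
      "region": "Dentate"
    },
    {
      "id": "Dentate_R",
      "hemisphere": "R",
      "region": "Dentate"
    },
    {
      "id": "supCereb_midline",
      "hemisphere": "midline",
      "region": "supCereb"
    }
  ]
}
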