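{
  "name": "dmn",
  "nodes": [
    {
      "id": "PCC_L",
      "hemisphere": "L",
      "region": "PCC"
    },
    {
      "id": "PCC_R",
      "hemisphere": "R",
      "region": "PCC"
    },
    {
      "id": "vmPFC_L",
      "hemisphere": "L",
      "region": "vmPFC"
    },
    {
      "id": "vmPFC_R",
      "hemisphere": "R",
      "region": "vmPFC"
    },
    {
      "id": "TPJ_L",
      "hemisphere": "L",
      "region": "TPJ"
    },
    {
      "id": "TPJ_R",
      "hemisphere": "R",
      "region": "TPJ"
    }
  ]
}
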