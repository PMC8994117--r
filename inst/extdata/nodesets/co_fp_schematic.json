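{
  "name": "co_fp",
  "nodes": [
    {
      "id": "dACC_midline",
      "hemisphere": "midline",
      "region": "CO_dACC"
    },
    {
      "id": "aIns_L",
      "hemisphere": "L",
      "region": "CO_aIns"
    },
    {
      "id": "aIns_R",
      "hemisphere": "R",
      "region": "CO_aIns"
    },
    {
      "id": "aPFC_L",
      "hemisphere": "L",
      "region": "CO_aPFC"
    },
    {
      "id": "aPFC_R",
      "hemisphere": "R",
      "region": "CO_aPFC"
    },
    {
      "id": "aThal_L",
      "hemisphere": "L",
      "region": "CO_aThal"
    },
    {
      "id": "aThal_R",
      "hemisphere": "R",
      "region": "CO_aThal"
    },
    {
      "id": "dlPFC_L",
      "hemisphere": "L",
      "region": "FP_dlPFC"
    },
    {
      "id": "dlPFC_R",
      "hemisphere": "R",
      "region": "FP_dlPFC"
    },
    {
      "id": "IPL_L",
      "hemisphere": "L",
      "region": "FP_IPL"
    },
    {
      "id": "IPL_R",
      "hemisphere": "R",
      "region": "FP_IPL"
    },
    {
      "id": "IPS_L",
      "hemisphere": "L",
      "region": "FP_IPS"
    },
    {
      "id": "IPS_R",
      "hemisphere": "R",
      "region": "FP_IPS"
    },
    {
      "id": "IFG_L",
      "hemisphere": "L",
      "region": "FP_IFG"
    },
    {
      "id": "IFG_R",
      "hemisphere": "R",
      "region": "FP_IFG"
    },
    {
      "id": "Precuneus_L",
      "hemisphere": "L",
      "region": "FP_Precuneus"
    },
    {
      "id": "Precuneus_R",
      "hemisphere": "R",
      "region": "FP_Precuneus"
    },
    {
      "id": "midCC_midline",
      "hemisphere": "midline",
      "region": "FP_midCC"
    }
  ]
}
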