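{
  "name": "language",
  "nodes": [
    {
      "id": "IFG_L_1",
      "hemisphere": "L",
      "region": "IFG"
    },
    {
      "id": "IFG_L_2",
      "hemisphere": "L",
      "region": "IFG"
    },
    {
      "id": "IFG_L_3",
      "hemisphere": "L",
      "region": "IFG"
    },
    {
      "id": "IFG_L_4",
      "hemisphere": "L",
      "region": "IFG"
    },
    {
      "id": "IFG_L_5",
      "hemisphere": "L",
      "region": "IFG"
    },
    {
      "id": "IFG_R_1",
      "hemisphere": "R",
      "region": "IFG"
    },
    {
      "id": "IFG_R_2",
      "hemisphere": "R",
      "region": "IFG"
    },
    {
      "id": "IFG_R_3",
      "hemisphere": "R",
      "region": "IFG"
    },
    {
      "id": "IFG_R_4",
      "hemisphere": "R",
      "region": "IFG"
    },
    {
      "id": "IFG_R_5",
      "hemisphere": "R",
      "region": "IFG"
    },
    {
      "id": "MFG_L_1",
      "hemisphere": "L",
      "region": "MFG"
    },
    {
      "id": "MFG_L_2",
      "hemisphere": "L",
      "region": "MFG"
    },
    {
      "id": "MFG_L_3",
      "hemisphere": "L",
      "region": "MFG"
    },
    {
      "id": "MFG_L_4",
      "hemisphere": "L",
      "region": "MFG"
    },
    {
      "id": "MFG_R_1",
      "hemisphere": "R",
      "region": "MFG"
    },
    {
      "id": "MFG_R_2",
      "hemisphere": "R",
      "region": "MFG"
    },
    {
      "id": "MFG_R_3",
      "hemisphere": "R",
      "region": "MFG"
    },
    {
      "id": "MFG_R_4",
      "hemisphere": "R",
      "region": "MFG"
    },
    {
      "id": "SFG_L_1",
      "hemisphere": "L",
      "region": "SFG"
    },
    {
      "id": "SFG_L_2",
      "hemisphere": "L",
      "region": "SFG"
    },
    {
      "id": "SFG_L_3",
      "hemisphere": "L",
      "region": "SFG"
    },
    {
      "id": "SFG_L_4",
      "hemisphere": "L",
      "region": "SFG"
    },
    {
      "id": "SFG_R_1",
      "hemisphere": "R",
      "region": "SFG"
    },
    {
      "id": "SFG_R_2",
      "hemisphere": "R",
      "region": "SFG"
    },
    {
      "id": "SFG_R_3",
      "hemisphere": "R",
      "region": "SFG"
    },
    {
      "id": "SFG_R_4",
      "hemisphere": "R",
      "region": "SFG"
    },
    {
      "id": "STG_L_1",
      "hemisphere": "L",
      "region": "STG"
    },
    {
      "id": "STG_L_2",
      "hemisphere": "L",
      "region": "STG"
    },
    {
      "id": "STG_L_3",
      "hemisphere": "L",
      "region": "STG"
    },
    {
      "id": "STG_L_4",
      "hemisphere": "L",
      "region": "STG"
    },
    {
      "id": "STG_R_1",
      "hemisphere": "R",
      "region": "STG"
    },
    {
      "id": "STG_R_2",
      "hemisphere": "R",
      "region": "STG"
    },
    {
      "id": "STG_R_3",
      "hemisphere": "R",
      "region": "STG"
    },
    {
      "id": "STG_R_4",
      "hemisphere": "R",
      "region": "STG"
    },
    {
      "id": "MTG_L_1",
      "hemisphere": "L",
      "region": "MTG"
    },
    {
      "id": "MTG_L_2",
      "hemisphere": "L",
      "region": "MTG"
    },
    {
      "id": "MTG_L_3",
      "hemisphere": "L",
      "region": "MTG"
    },
    {
      "id": "MTG_L_4",
      "hemisphere": "L",
      "region": "MTG"
    },
    {
      "id": "MTG_R_1",
      "hemisphere": "R",
      "region": "MTG"
    },
    {
      "id": "MTG_R_2",
      "hemisphere": "R",
      "region": "MTG"
    },
    {
      "id": "MTG_R_3",
      "hemisphere": "R",
      "region": "MTG"
    },
    {
      "id": "MTG_R_4",
      "hemisphere": "R",
      "region": "MTG"
    },
    {
      "id": "ITG_L_1",
      "hemisphere": "L",
      "region": "ITG"
    },
    {
      "id": "ITG_L_2",
      "hemisphere": "L",
      "region": "ITG"
    },
    {
      "id": "ITG_L_3",
      "hemisphere": "L",
      "region": "ITG"
    },
    {
      "id": "ITG_R_1",
      "hemisphere": "R",
      "region": "ITG"
    },
    {
      "id": "ITG_R_2",
      "hemisphere": "R",
      "region": "ITG"
    },
    {
      "id": "ITG_R_3",
      "hemisphere": "R",
      "region": "ITG"
    },
    {
      "id": "PrG_L_1",
      "hemisphere": "L",
      "region": "PrG"
    },
    {
      "id": "PrG_L_2",
      "hemisphere": "L",
      "region": "PrG"
    },
    {
      "id": "PrG_L_3",
      "hemisphere": "L",
      "region": "PrG"
    },
    {
      "id": "PrG_R_1",
      "hemisphere": "R",
      "region": "PrG"
    },
    {
      "id": "PrG_R_2",
      "hemisphere": "R",
      "region": "PrG"
    },
    {
      "id": "PrG_R_3",
      "hemisphere": "R",
      "region": "PrG"
    },
    {
      "id": "PoG_L_1",
      "hemisphere": "L",
      "region": "PoG"
    },
    {
      "id": "PoG_L_2",
      "hemisphere": "L",
      "region": "PoG"
    },
    {
      "id": "PoG_L_3",
      "hemisphere": "L",
      "region": "PoG"
    },
    {
      "id": "PoG_R_1",
      "hemisphere": "R",
      "region": "PoG"
    },
    {
      "id": "PoG_R_2",
      "hemisphere": "R",
      "region": "PoG"
    },
    {
      "id": "PoG_R_3",
      "hemisphere": "R",
      "region": "PoG"
    },
    {
      "id": "IPL_L_1",
      "hemisphere": "L",
      "region": "IPL"
    },
    {
      "id": "IPL_L_2",
      "hemisphere": "L",
      "region": "IPL"
    },
    {
      "id": "IPL_L_3",
      "hemisphere": "L",
      "region": "IPL"
    },
    {
      "id": "IPL_L_4",
      "hemisphere": "L",
      "region": "IPL"
    },
    {
      "id": "IPL_R_1",
      "hemisphere": "R",
      "region": "IPL"
    },
    {
      "id": "IPL_R_2",
      "hemisphere": "R",
      "region": "IPL"
    },
    {
      "id": "IPL_R_3",
      "hemisphere": "R",
      "region": "IPL"
    },
    {
      "id": "IPL_R_4",
      "hemisphere": "R",
      "region": "IPL"
    }
  ]
}
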