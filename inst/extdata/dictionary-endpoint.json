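{
  "entries": {
    "Zeta Potential": "ZETA POTENTIAL",
    "zeta-potential": "ZETA POTENTIAL",
    "Cell Viability": "CELL VIABILITY",
    "viability": "CELL VIABILITY",
    "CFE": "COLONY FORMING EFFICIENCY",
    "colony forming efficiency": "COLONY FORMING EFFICIENCY"
  },
  "annotations": {
    "ZETA POTENTIAL": [
      {"vocabulary": "NPO", "id": "NPO_1302", "label": "zeta potential"}
    ],
    "COLONY FORMING EFFICIENCY": [
      {"vocabulary": "BAO", "id": "BAO:0002805", "label": "colony formation assay"}
    ]
  }
}
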