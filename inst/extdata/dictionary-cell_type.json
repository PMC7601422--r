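{
  "entries": {
    "BEAS 2B": "BEAS-2B",
    "Beas 2B": "BEAS-2B",
    "BEAS -2B": "BEAS-2B",
    "A 549": "A549",
    "a549 cells": "A549"
  },
  "annotations": {
    "BEAS-2B": [
      {"vocabulary": "BTO", "id": "BTO:0001980", "label": "BEAS-2B cell"},
      {"vocabulary": "CLO", "id": "CLO:0001731", "label": "BEAS-2B cell line"}
    ],
    "A549": [
      {"vocabulary": "BTO", "id": "BTO:0000018", "label": "A-549 cell"}
    ]
  }
}
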