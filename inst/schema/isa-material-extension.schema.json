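{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ISA-JSON investigation skeleton with nanomaterial component/linkage extension",
  "description": "Reconstructed extension layout: a material carries components, each with a role (core, coating, ...) and linkages to sibling constituents. This schema is this package's own reconstruction of a role-plus-linkage component model, not an upstream artifact.",
  "type": "object",
  "required": ["identifier", "studies"],
  "properties": {
    "identifier": {"type": "string"},
    "title": {"type": "string"},
    "studies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["identifier", "materials", "assays"],
        "properties": {
          "identifier": {"type": "string"},
          "title": {"type": "string"},
          "materials": {
            "type": "object",
            "required": ["sources"],
            "properties": {
              "sources": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["@id", "name"],
                  "properties": {
                    "@id": {"type": "string"},
                    "name": {"type": "string"},
                    "type": {"type": "string"},
                    "characteristics": {
                      "type": "array",
                      "items": {
                        "type": "object",
                        "properties": {
                          "category": {"type": "object"},
                          "value": {"type": "object"}
                        }
                      }
                    },
                    "components": {
                      "type": "array",
                      "items": {
                        "type": "object",
                        "required": ["@id", "role"],
                        "properties": {
                          "@id": {"type": "string"},
                          "role": {
                            "enum": ["MAIN_CONSTITUENT", "IMPURITY", "ADDITIVE",
                                     "CORE", "COATING", "FUNCTIONALISATION",
                                     "OTHER"]
                          },
                          "name": {"type": "string"},
                          "linkages": {
                            "type": "array",
                            "items": {
                              "type": "object",
                              "required": ["target", "relation"],
                              "properties": {
                                "target": {"type": "string"},
                                "relation": {"type": "string"}
                              }
                            }
                          }
                        }
                      }
                    }
                  }
                }
              },
              "samples": {"type": "array"},
              "otherMaterials": {"type": "array"}
            }
          },
          "assays": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["@id", "measurementType", "dataFiles",
                           "processSequence"],
              "properties": {
                "@id": {"type": "string"},
                "measurementType": {"type": "object"},
                "technologyType": {"type": "object"},
                "dataFiles": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["@id", "name", "type"],
                    "properties": {
                      "@id": {"type": "string"},
                      "name": {"type": "string"},
                      "type": {"type": "string"},
                      "result": {"type": "object"},
                      "factorValues": {
                        "type": "array",
                        "items": {
                          "type": "object",
                          "required": ["category", "value"],
                          "properties": {
                            "category": {"type": "object"},
                            "value": {"type": ["number", "string"]},
                            "unit": {"type": "object"}
                          }
                        }
                      }
                    }
                  }
                },
                "processSequence": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["@id", "inputs", "outputs"],
                    "properties": {
                      "@id": {"type": "string"},
                      "executesProtocol": {"type": "object"},
                      "parameterValues": {"type": "array"},
                      "inputs": {"type": "array"},
                      "outputs": {"type": "array"}
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
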