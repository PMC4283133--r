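{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "vmodel annotated events interchange document",
  "type": "object",
  "additionalProperties": false,
  "required": ["schema_version", "patients"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "patients": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["patient_id", "events"],
        "properties": {
          "patient_id": {"type": "string"},
          "anchor_date": {"type": "string", "format": "date"},
          "events": {
            "type": "array",
            "items": {
              "type": "object",
              "additionalProperties": false,
              "required": ["event_id", "semantic_type", "appearance_index"],
              "properties": {
                "event_id": {"type": "string"},
                "text": {"type": "string"},
                "semantic_type": {
                  "enum": ["Purpose", "Sx", "Dx", "Finding", "Drug", "Op",
                           "Other", "Plan", "Test", "Tx", "Adm", "Death",
                           "Disch", "Visit"]
                },
                "raw_time": {"type": "string"},
                "appearance_index": {"type": "integer", "minimum": 0},
                "causal_links": {
                  "type": "array",
                  "items": {"type": "string"}
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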