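{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "prevcal/scenario/v1",
  "title": "Synthetic validation scenario",
  "type": "object",
  "required": ["name", "runs"],
  "properties": {
    "name": {"type": "string"},
    "expected_flags": {"type": "array", "items": {"type": "string"}},
    "runs": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["label", "profile"],
        "properties": {
          "label": {"type": "string"},
          "profile": {
            "type": "object",
            "required": ["sen", "spe", "pre", "n"],
            "properties": {
              "sen": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
              "spe": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
              "pre": {"type": "number", "minimum": 0, "maximum": 1},
              "n": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          "counts": {"$ref": "prevcal/confusion_matrix/v1"},
          "labels_file": {"type": "string"}
        }
      }
    }
  }
}
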