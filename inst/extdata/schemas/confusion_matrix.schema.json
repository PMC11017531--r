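{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "prevcal/confusion_matrix/v1",
  "title": "Binary confusion matrix",
  "type": "object",
  "required": ["tp", "fn", "fp", "tn"],
  "properties": {
    "tp": {"type": "number", "minimum": 0},
    "fn": {"type": "number", "minimum": 0},
    "fp": {"type": "number", "minimum": 0},
    "tn": {"type": "number", "minimum": 0},
    "metadata": {
      "type": "object",
      "properties": {
        "name": {"type": "string"},
        "description": {"type": "string"},
        "calibrated": {"type": "boolean"}
      }
    }
  }
}
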