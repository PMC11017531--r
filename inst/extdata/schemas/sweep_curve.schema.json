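{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "prevcal/sweep_curve/v1",
  "title": "Prevalence-sweep curve (CSV companion schema)",
  "description": "The CSV carries '# metric:', '# sen:', '# spe:' metadata lines followed by a prevalence,value table; this schema describes its JSON equivalent.",
  "type": "object",
  "required": ["metric", "sen", "spe", "prevalence", "value"],
  "properties": {
    "metric": {"type": "string"},
    "sen": {"type": "number", "minimum": 0, "maximum": 1},
    "spe": {"type": "number", "minimum": 0, "maximum": 1},
    "prevalence": {
      "type": "array",
      "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}
    },
    "value": {"type": "array", "items": {"type": "number"}}
  }
}
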