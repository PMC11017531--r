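{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "prevcal/comparison_report/v1",
  "title": "Two-run validation comparison report",
  "type": "object",
  "required": ["schema", "runs", "sen_variation", "spe_variation",
               "raw_metrics", "calibrated_metrics", "target_prevalence",
               "delta_prevalence", "verdict", "flags"],
  "properties": {
    "schema": {"const": "prevcal/comparison_report/v1"},
    "runs": {
      "type": "array",
      "minItems": 2,
      "maxItems": 2,
      "items": {
        "type": "object",
        "required": ["label", "n", "prevalence"],
        "properties": {
          "label": {"type": "string", "minLength": 1},
          "source": {"type": ["string", "null"]},
          "n": {"type": "number", "exclusiveMinimum": 0},
          "prevalence": {"type": "number", "minimum": 0, "maximum": 1},
          "sen": {"type": ["number", "null"]},
          "spe": {"type": ["number", "null"]}
        }
      }
    },
    "sen_variation": {"enum": ["increase", "decrease", "constant", "undefined"]},
    "spe_variation": {"enum": ["increase", "decrease", "constant", "undefined"]},
    "raw_metrics": {"$ref": "#/definitions/metric_table"},
    "calibrated_metrics": {"$ref": "#/definitions/metric_table"},
    "target_prevalence": {"type": "number", "minimum": 0, "maximum": 1},
    "delta_prevalence": {"type": "number", "minimum": 0, "maximum": 1},
    "verdict": {"enum": ["better", "worse", "trade_off", "undefined"]},
    "flags": {
      "type": "array",
      "items": {"enum": ["prevalence_shift", "raw_metric_contradiction"]}
    },
    "shift_threshold": {"type": "number", "minimum": 0},
    "tol": {"type": "number", "minimum": 0}
  },
  "definitions": {
    "metric_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["metric", "values", "variation"],
        "properties": {
          "metric": {"type": "string"},
          "values": {"type": "object", "additionalProperties": {"type": ["number", "null"]}},
          "variation": {"enum": ["increase", "decrease", "constant", "undefined"]}
        }
      }
    }
  }
}
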