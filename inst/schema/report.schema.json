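{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "KymoDwell pipeline report",
  "type": "object",
  "required": ["seed", "reference", "variants", "comparisons"],
  "properties": {
    "seed": { "type": "integer" },
    "reference": { "type": "string" },
    "variants": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["name", "n_events", "end_residence", "velocity",
                     "run_length"],
        "properties": {
          "name": { "type": "string" },
          "n_events": { "type": "integer" },
          "n_discarded_crossing": { "type": "integer" },
          "end_residence": {
            "type": "object",
            "required": ["n", "mean", "sem"],
            "properties": {
              "n": { "type": "integer" },
              "mean": { "type": ["number", "null"] },
              "sem": { "type": ["number", "null"] },
              "dwell_mle": { "type": ["number", "null"] }
            }
          },
          "velocity": {
            "type": "object",
            "required": ["n", "mean", "sem"]
          },
          "run_length": {
            "type": "object",
            "required": ["n", "mean", "sem"]
          }
        }
      }
    },
    "comparisons": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["variant", "reference"],
        "properties": {
          "variant": { "type": "string" },
          "reference": { "type": "string" },
          "ks_D": { "type": "number" },
          "ks_p": { "type": "number" },
          "n1": { "type": "integer" },
          "n2": { "type": "integer" },
          "fold_change": { "type": "number" },
          "fold_change_ci": {
            "type": "array",
            "items": { "type": "number" },
            "minItems": 2,
            "maxItems": 2
          },
          "note": { "type": "string" }
        }
      }
    }
  }
}
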