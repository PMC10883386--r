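{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ahltools report formats",
  "type": "object",
  "properties": {
    "screen": {
      "type": "object",
      "required": ["command", "inputs", "species", "stage_counts", "n_features", "n_clusters", "config"],
      "properties": {
        "command": {"const": "screen"},
        "inputs": {
          "type": "object",
          "required": ["sample", "control"],
          "properties": {"sample": {"type": "string"}, "control": {"type": "string"}}
        },
        "species": {"type": "string"},
        "stage_counts": {
          "type": "object",
          "required": ["scanned", "screened", "confirmed", "masses", "peaks", "retained"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "n_features": {"type": "integer", "minimum": 0},
        "n_clusters": {"type": "integer", "minimum": 0},
        "config": {"type": "object"}
      }
    },
    "mine": {
      "type": "object",
      "required": ["command", "n_assemblies", "n_species", "families", "config"],
      "properties": {
        "command": {"const": "mine"},
        "n_assemblies": {"type": "integer", "minimum": 0},
        "n_species": {"type": "integer", "minimum": 0},
        "families": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["family", "n_species", "median", "mean", "min", "max",
                         "n_with_at_least_one", "n_with_exactly_one"]
          }
        },
        "blast": {
          "type": ["object", "null"],
          "properties": {
            "n_hits": {"type": "integer"},
            "n_unique_species": {"type": "integer"}
          }
        },
        "config": {"type": "object"}
      }
    },
    "simulate": {
      "type": "object",
      "required": ["kind", "files"],
      "properties": {
        "kind": {"enum": ["ms_run", "cohort"]},
        "files": {"type": "object", "additionalProperties": {"type": "string"}}
      }
    }
  }
}
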