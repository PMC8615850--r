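{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dbsorient detection report",
  "type": "object",
  "required": ["tool", "version", "timestamp", "lead_profile",
               "angle_convention", "polar_deg", "gate",
               "refined_tip_world", "refined_unit_dir", "config"],
  "properties": {
    "tool": {"const": "dbsorient"},
    "version": {"type": "string"},
    "timestamp": {"type": "string"},
    "lead_profile": {"type": "string"},
    "angle_convention": {"type": "string"},
    "polar_deg": {"type": "number", "minimum": 0, "maximum": 90},
    "gate": {"enum": ["ok", "warn", "refuse"]},
    "refined_tip_world": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3},
    "refined_unit_dir": {"type": "array", "items": {"type": "number"}, "minItems": 3, "maxItems": 3},
    "config": {"type": "object"},
    "marker_center_world": {"type": "array", "items": {"type": "number"}},
    "marker_slice_offset_mm": {"type": "number"},
    "candidate_pair": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2},
    "second_harmonic_amplitude_HU": {"type": "number", "minimum": 0},
    "methods": {
      "type": "object",
      "properties": {
        "COM": {"$ref": "#/definitions/method"},
        "COMsagittal": {"$ref": "#/definitions/method"},
        "ASM": {"$ref": "#/definitions/method"},
        "STARS": {"$ref": "#/definitions/method"}
      }
    },
    "final_orientation_deg": {"type": "number", "exclusiveMinimum": -180, "maximum": 180},
    "mismatch": {"type": "boolean"},
    "deciding_method": {"enum": ["COM", "COMsagittal", "STARS", "ASM"]},
    "confidence": {"enum": ["ok", "reduced"]}
  },
  "allOf": [
    {
      "if": {"properties": {"gate": {"const": "refuse"}}},
      "then": {"not": {"required": ["final_orientation_deg"]}}
    }
  ],
  "definitions": {
    "method": {
      "type": "object",
      "required": ["method", "chosen_theta_deg", "margin", "degenerate"],
      "properties": {
        "method": {"type": "string"},
        "chosen_theta_deg": {"type": "number", "minimum": 0, "exclusiveMaximum": 360},
        "margin": {"type": "number", "minimum": 0},
        "degenerate": {"type": "boolean"}
      }
    }
  }
}
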