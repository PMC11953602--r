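{
  "$comment": "Schema of the milestone knowledge-base JSON document",
  "type": "object",
  "required": ["coverage_range", "questions", "months"],
  "properties": {
    "coverage_range": {
      "type": "array", "items": {"type": "integer", "minimum": 1},
      "minItems": 2, "maxItems": 2,
      "description": "Closed range [min_month, max_month] of completed months covered"
    },
    "quotas": {
      "type": "object",
      "description": "Declared question count per language domain",
      "properties": {
        "sensory_reception": {"type": "integer", "minimum": 0},
        "language_perception": {"type": "integer", "minimum": 0},
        "production": {"type": "integer", "minimum": 0},
        "pragmatics": {"type": "integer", "minimum": 0}
      }
    },
    "questions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "text", "domain", "applicable_months", "severity_class"],
        "properties": {
          "id": {"type": "string"},
          "text": {"type": "string"},
          "domain": {"enum": ["sensory_reception", "language_perception", "production", "pragmatics"]},
          "applicable_months": {"type": "array", "items": {"type": "integer", "minimum": 1}, "minItems": 1},
          "severity_class": {"enum": ["warning", "alarm"]}
        }
      }
    },
    "months": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["month", "question_ids"],
        "properties": {
          "month": {"type": "integer", "minimum": 1},
          "question_ids": {"type": "array", "items": {"type": "string"}, "minItems": 3, "maxItems": 6}
        }
      }
    },
    "metadata": {"type": "object"}
  }
}
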