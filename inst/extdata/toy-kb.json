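{
  "coverage_range": [14, 15],
  "quotas": {
    "sensory_reception": 0,
    "language_perception": 1,
    "production": 3,
    "pragmatics": 2
  },
  "questions": [
    {"id": "q1", "text": "Produces first two-word combinations", "domain": "production",
     "applicable_months": [14], "severity_class": "warning"},
    {"id": "q2", "text": "Points to request or show objects", "domain": "pragmatics",
     "applicable_months": [14], "severity_class": "warning"},
    {"id": "q3", "text": "Understands simple one-step instructions", "domain": "language_perception",
     "applicable_months": [14, 15], "severity_class": "warning"},
    {"id": "q4", "text": "Uses at least ten recognizable words", "domain": "production",
     "applicable_months": [15], "severity_class": "warning"},
    {"id": "q5", "text": "Imitates new words spontaneously", "domain": "production",
     "applicable_months": [15], "severity_class": "warning"},
    {"id": "q6", "text": "Responds to own name consistently", "domain": "pragmatics",
     "applicable_months": [15], "severity_class": "alarm"}
  ],
  "months": [
    {"month": 14, "question_ids": ["q1", "q2", "q3"]},
    {"month": 15, "question_ids": ["q3", "q4", "q5", "q6"]}
  ]
}
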