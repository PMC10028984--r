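{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "stripedyn scenario configuration",
  "description": "An optogenetic stimulus protocol plus the nuclear-cycle schedule. Times are minutes since the start of NC10 (= illumination start for NC10 protocols); lengths are micrometres.",
  "type": "object",
  "required": ["intensity", "on_intervals", "mask", "schedule"],
  "properties": {
    "name": { "type": "string" },
    "intensity": {
      "type": "number",
      "minimum": 0,
      "description": "relative light dose; high = 1.0, low = 0.125"
    },
    "on_intervals": {
      "type": "array",
      "description": "sorted, non-overlapping [start, end] pairs within [0, gastrulation_time]",
      "items": {
        "type": "array",
        "items": { "type": "number" },
        "minItems": 2,
        "maxItems": 2
      }
    },
    "mask": {
      "type": "array",
      "description": "illuminated x-intervals in micrometres; use null or +/-1e308 for half-planes",
      "items": {
        "type": "array",
        "items": { "type": ["number", "null"] },
        "minItems": 2,
        "maxItems": 2
      }
    },
    "pulse_cadence": {
      "type": "string",
      "description": "descriptive metadata; the physical 0.6 s / 30 s pulsing is treated as a continuous input of the same average dose"
    },
    "schedule": {
      "type": "object",
      "required": ["cycles", "gastrulation_time"],
      "properties": {
        "cycles": {
          "type": "array",
          "description": "interphase records; mitoses fill the gaps between consecutive interphases",
          "items": {
            "type": "object",
            "required": ["cycle", "start", "end"],
            "properties": {
              "cycle": { "type": "integer", "minimum": 10, "maximum": 14 },
              "start": { "type": "number" },
              "end": { "type": "number" }
            }
          }
        },
        "gastrulation_time": { "type": "number" }
      }
    }
  }
}
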