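{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ventasync analysis report",
  "type": "object",
  "required": [
    "basic_info",
    "diagnostic_reference",
    "prompts_findings",
    "ventilator_parameters",
    "waveform_excerpt"
  ],
  "properties": {
    "basic_info": { "type": "object" },
    "diagnostic_reference": {
      "type": "object",
      "required": ["window_s", "window_end_s", "ai_pct", "severe", "event_counts"],
      "properties": {
        "window_s": { "type": "number", "exclusiveMinimum": 0 },
        "window_end_s": { "type": "number" },
        "ai_pct": { "type": ["number", "null"], "minimum": 0 },
        "severe": { "type": "boolean" },
        "event_counts": {
          "type": "object",
          "required": ["double_trigger", "ineffective_trigger"],
          "properties": {
            "double_trigger": { "type": "integer", "minimum": 0 },
            "ineffective_trigger": { "type": "integer", "minimum": 0 }
          }
        }
      }
    },
    "prompts_findings": {
      "type": "array",
      "items": { "type": "string" },
      "minItems": 1
    },
    "ventilator_parameters": {
      "type": "object",
      "properties": {
        "peak_pressure_cmh2o": { "type": ["number", "null"] },
        "peep_cmh2o": { "type": ["number", "null"] },
        "total_resp_rate_per_min": { "type": ["number", "null"] },
        "tidal_volume_ml": { "type": ["number", "null"] },
        "minute_ventilation_l": { "type": ["number", "null"] }
      }
    },
    "waveform_excerpt": {
      "type": "object",
      "required": ["start_index", "end_index"],
      "properties": {
        "start_index": { "type": "integer", "minimum": 1 },
        "end_index": { "type": "integer", "minimum": 1 }
      }
    }
  }
}
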