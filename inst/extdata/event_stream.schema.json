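{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "akicds patient event stream row",
  "description": "One row of a flat patient event stream (CSV columns or one JSON-lines object). Timestamps are ISO-8601, compared in UTC. Creatinine is in umol/L unless the reader is told mg/dL.",
  "type": "object",
  "required": ["record_kind", "patient_id", "timestamp"],
  "properties": {
    "record_kind": {"enum": ["lab", "medication", "fluid", "vital", "encounter"]},
    "patient_id": {"type": "string", "minLength": 1},
    "encounter_id": {"type": ["string", "null"]},
    "timestamp": {"type": "string", "description": "lab collected_at / medication ordered_at / fluid-vital recorded_at / encounter admit_time"},
    "end_timestamp": {"type": ["string", "null"], "description": "medication discontinued_at / encounter discharge_time"},
    "analyte": {"enum": ["creatinine", "urea", "sodium", "potassium", "bicarbonate", "wbc", "urinalysis", "urine_protein", "other", null]},
    "setting": {"enum": ["hospital", "community", null]},
    "drug_name": {"type": ["string", "null"]},
    "kind": {"enum": ["intake_iv", "intake_oral", "output_urine", "output_other", "heart_rate", "systolic_bp", "diastolic_bp", null]},
    "unit_type": {"enum": ["medical", "surgical", null]},
    "unit_name": {"type": ["string", "null"]},
    "value": {"type": ["number", "string", "null"], "description": "lab value / fluid volume (mL) / vital value; positive for quantitative analytes and vitals, nonnegative for fluids"}
  }
}
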